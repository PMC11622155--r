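meadow,variable,horizon,projected,donor
Wallis Lake,AvTemp,2030,24.59,Port Hacking
Wallis Lake,AvTemp,2040,26.59,NA
Wallis Lake,AvTemp,2050,28.59,NA
Port Stephens,AvTemp,2030,23.52,Wallis Lake
Port Stephens,AvTemp,2040,25.52,NA
Port Stephens,AvTemp,2050,27.52,NA
Lake Macquarie,AvTemp,2030,25.39,NA
Lake Macquarie,AvTemp,2040,27.39,NA
Lake Macquarie,AvTemp,2050,29.39,NA
Brisbane Water,AvTemp,2030,24.10,Lake Macquarie
Brisbane Water,AvTemp,2040,26.10,NA
Brisbane Water,AvTemp,2050,28.10,NA
Pittwater,AvTemp,2030,24.61,Port Hacking
Pittwater,AvTemp,2040,26.61,NA
Pittwater,AvTemp,2050,28.61,NA
Sydney Harbour,AvTemp,2030,25.60,NA
Sydney Harbour,AvTemp,2040,27.60,NA
Sydney Harbour,AvTemp,2050,29.60,NA
Botany Bay,AvTemp,2030,23.80,Lake Macquarie
Botany Bay,AvTemp,2040,25.80,NA
Botany Bay,AvTemp,2050,27.80,NA
Port Hacking,AvTemp,2030,26.02,NA
Port Hacking,AvTemp,2040,28.02,NA
Port Hacking,AvTemp,2050,30.02,NA
Batemans Bay,AvTemp,2030,23.43,Pittwater
Batemans Bay,AvTemp,2040,25.43,NA
Batemans Bay,AvTemp,2050,27.43,NA
Wagonga Inlet,AvTemp,2030,22.44,Botany Bay
Wagonga Inlet,AvTemp,2040,24.44,Sydney Harbour
Wagonga Inlet,AvTemp,2050,26.44,NA
Bermagui,AvTemp,2030,21.34,Batemans Bay
Bermagui,AvTemp,2040,23.34,Pittwater
Bermagui,AvTemp,2050,25.34,NA
Merimbula,AvTemp,2030,21.50,Batemans Bay
Merimbula,AvTemp,2040,23.50,Pittwater
Merimbula,AvTemp,2050,25.50,NA
Pambula,AvTemp,2030,21.41,Batemans Bay
Pambula,AvTemp,2040,23.41,Pittwater
Pambula,AvTemp,2050,25.41,NA
Wallis Lake,MaxTemp,2030,31.51,NA
Wallis Lake,MaxTemp,2040,33.51,NA
Wallis Lake,MaxTemp,2050,35.51,NA
Port Stephens,MaxTemp,2030,29.77,Wallis Lake
Port Stephens,MaxTemp,2040,31.77,NA
Port Stephens,MaxTemp,2050,33.77,NA
Lake Macquarie,MaxTemp,2030,30.00,Wallis Lake
Lake Macquarie,MaxTemp,2040,32.00,NA
Lake Macquarie,MaxTemp,2050,34.00,NA
Brisbane Water,MaxTemp,2030,28.89,Batemans Bay
Brisbane Water,MaxTemp,2040,30.89,Botany Bay
Brisbane Water,MaxTemp,2050,32.89,NA
Pittwater,MaxTemp,2030,26.36,Brisbane Water
Pittwater,MaxTemp,2040,28.36,Port Stephens
Pittwater,MaxTemp,2050,30.36,Botany Bay
Sydney Harbour,MaxTemp,2030,29.10,Wallis Lake
Sydney Harbour,MaxTemp,2040,31.10,Botany Bay
Sydney Harbour,MaxTemp,2050,33.10,NA
Botany Bay,MaxTemp,2030,32.20,NA
Botany Bay,MaxTemp,2040,34.20,NA
Botany Bay,MaxTemp,2050,36.20,NA
Port Hacking,MaxTemp,2030,29.93,Wallis Lake
Port Hacking,MaxTemp,2040,31.93,NA
Port Hacking,MaxTemp,2050,33.93,NA
Batemans Bay,MaxTemp,2030,30.15,Wallis Lake
Batemans Bay,MaxTemp,2040,32.15,NA
Batemans Bay,MaxTemp,2050,34.15,NA
Wagonga Inlet,MaxTemp,2030,29.95,Wallis Lake
Wagonga Inlet,MaxTemp,2040,31.95,NA
Wagonga Inlet,MaxTemp,2050,33.95,NA
Bermagui,MaxTemp,2030,27.36,Brisbane Water
Bermagui,MaxTemp,2040,29.36,Wallis Lake
Bermagui,MaxTemp,2050,31.36,Botany Bay
Merimbula,MaxTemp,2030,27.05,Brisbane Water
Merimbula,MaxTemp,2040,29.05,Wallis Lake
Merimbula,MaxTemp,2050,31.05,Botany Bay
Pambula,MaxTemp,2030,27.33,Brisbane Water
Pambula,MaxTemp,2040,29.33,Wallis Lake
Pambula,MaxTemp,2050,31.33,Botany Bay
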