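forest_type,label,goshawk_pct,sparrowhawk_pct,buzzard_pct,forest_area_pct
1,Old mixed eucalyptus stands,39.2,47.6,43.8,21.0
2,Mixed eucalyptus stands,43.1,39.6,40.8,23.9
3,Burned eucalyptus stands,5.9,5.5,4.6,4.1
4,Monospecific eucalyptus stands,8.5,3.7,4.2,12.2
5,Forests with scattered trees,0.0,0.0,1.2,3.2
6,Deciduous riverbank forests,0.0,0.0,0.0,1.7
7,"Oak, chestnut and cork oak woods",2.0,0.0,1.5,4.7
8,Pine forests,0.0,0.6,0.0,5.0
9,Burned pine forests,0.0,0.0,0.0,0.2
10,Acacia forests,0.0,1.8,0.0,0.4
11,Young plantations,0.7,1.2,3.5,16.6
12,Recently logged forests,0.7,0.0,0.4,7.1
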