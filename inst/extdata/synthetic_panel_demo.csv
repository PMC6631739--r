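country,iso3,region,income_group,year,stillbirths,live_births,neonatal_deaths,neonatal_mortality_rate,life_expectancy
SYN001,NA,SA,lower-middle+low,2000,417.73411875963416,21385.1338596861,482.68963004131575,22.571269986354945,58.7024748712093
SYN002,NA,SSA,lower-middle+low,2000,283.42041300668336,24771.933977283934,357.61719472393844,14.436385752193443,59.65067221729706
SYN003,NA,SEA,lower-middle+low,2000,6964.284897590064,384490.72685032827,5600.049859723699,14.56485025165157,58.26924529308662
SYN004,NA,NAME,lower-middle+low,2000,263698.2450020226,18024192.150868963,411008.640474395,22.803165713841988,60.05749299714828
SYN005,NA,SA,lower-middle+low,2000,1388.8480119757867,28049.227838087514,1604.0707760589942,57.1876981897112,51.38631157792542
SYN006,NA,SSA,lower-middle+low,2000,17323.092186810398,558339.1036260724,21966.193492764076,39.34202951236449,53.364386975522876
SYN007,NA,DR,high+upper-middle,2000,1122.1470442024422,91423.65275043387,2730.257283583235,29.863795652928317,74.54665362893313
SYN008,NA,EA,high+upper-middle,2000,980.5993138793192,67867.8646700283,957.9228638188699,14.114527817786293,73.71875333735356
SYN009,NA,LAC,high+upper-middle,2000,382.9891698643227,32704.651705665958,474.61022437984445,14.512009748681104,75.7746484925356
SYN010,NA,CCA,high+upper-middle,2000,335.704433498967,26646.296152067003,445.29037655993824,16.71115467675969,76.28918648785269
SYN011,NA,DR,high+upper-middle,2000,122.79028149440259,16034.818796080108,145.32803889408234,9.063279151592871,78.19594886303015
SYN012,NA,EA,high+upper-middle,2000,1204.7403253560185,156956.33443548315,1468.556304262076,9.356464073552416,75.83586270933873
SYN001,NA,SA,lower-middle+low,2015,10100.320814236095,694983.1223031734,8804.610584714048,12.668812093645636,58.16306865560964
SYN002,NA,SSA,lower-middle+low,2015,1326.169375708224,155795.47748097422,1348.1954387918963,8.653623716109077,59.775625446129624
SYN003,NA,SEA,lower-middle+low,2015,10200.249222227583,756915.1332226951,9315.526845566024,12.307227635816426,57.981383157603176
SYN004,NA,NAME,lower-middle+low,2015,141418.53065387366,12992177.767613158,138476.5675487193,10.658456959687932,59.892775417225586
SYN005,NA,SA,lower-middle+low,2015,2354.247836249117,63906.55887057979,3955.2842645490236,61.89167957797661,53.747197546834194
SYN006,NA,SSA,lower-middle+low,2015,7997.259977947394,346450.27258585085,7938.0133562468445,22.91241769561545,55.42715625015798
SYN007,NA,DR,high+upper-middle,2015,400.3154482478934,49945.684327406285,522.2113950355975,10.455585944370549,75.97472427408759
SYN008,NA,EA,high+upper-middle,2015,1149.0928979537102,121790.82134978064,1405.592839276836,11.541040808321698,72.64489841891776
SYN009,NA,LAC,high+upper-middle,2015,7896.883301536626,1032679.543412575,10508.222590569005,10.17568582393306,75.53460234064913
SYN010,NA,CCA,high+upper-middle,2015,11965.3913979975,1454432.2693692,13931.456293959842,9.578621560701507,75.88648475617052
SYN011,NA,DR,high+upper-middle,2015,239.5468404885721,47904.612037372324,287.8554334253783,6.00892943670665,76.15792653861577
SYN012,NA,EA,high+upper-middle,2015,1504.2636907019833,300120.86657149333,1903.109280720351,6.341142828424433,76.36391046354609
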