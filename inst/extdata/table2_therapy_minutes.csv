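quarter,indicator,sector,value
1996_3,mean_therapy_minutes,CCC,66.0
1996_4,mean_therapy_minutes,CCC,64.3
1997_1,mean_therapy_minutes,CCC,65.6
1997_2,mean_therapy_minutes,CCC,75.8
1997_3,mean_therapy_minutes,CCC,72.2
1997_4,mean_therapy_minutes,CCC,75.2
1998_1,mean_therapy_minutes,CCC,80.7
1998_2,mean_therapy_minutes,CCC,81.8
1998_3,mean_therapy_minutes,CCC,80.8
1998_4,mean_therapy_minutes,CCC,80.2
1999_1,mean_therapy_minutes,CCC,89.8
1999_2,mean_therapy_minutes,CCC,80.2
1999_3,mean_therapy_minutes,CCC,80.0
1999_4,mean_therapy_minutes,CCC,82.2
2000_1,mean_therapy_minutes,CCC,86.2
2000_2,mean_therapy_minutes,CCC,84.0
2000_3,mean_therapy_minutes,CCC,87.2
2000_4,mean_therapy_minutes,CCC,87.6
2001_1,mean_therapy_minutes,CCC,85.2
2001_2,mean_therapy_minutes,CCC,88.0
2001_3,mean_therapy_minutes,CCC,85.4
2001_4,mean_therapy_minutes,CCC,85.7
2002_1,mean_therapy_minutes,CCC,88.6
2002_2,mean_therapy_minutes,CCC,98.8
2002_3,mean_therapy_minutes,CCC,96.4
2002_4,mean_therapy_minutes,CCC,96.9
2003_1,mean_therapy_minutes,CCC,97.3
2003_2,mean_therapy_minutes,CCC,100.2
2003_3,mean_therapy_minutes,CCC,95.8
2003_4,mean_therapy_minutes,CCC,98.9
2004_1,mean_therapy_minutes,CCC,106.4
2004_2,mean_therapy_minutes,CCC,108.6
2004_3,mean_therapy_minutes,CCC,110.3
2004_4,mean_therapy_minutes,CCC,110.7
2005_1,mean_therapy_minutes,CCC,112.1
2005_2,mean_therapy_minutes,CCC,117.8
2005_3,mean_therapy_minutes,CCC,118.8
2005_3,mean_therapy_minutes,LTC,14.8
2005_4,mean_therapy_minutes,CCC,116.1
2005_4,mean_therapy_minutes,LTC,10.3
2006_1,mean_therapy_minutes,CCC,119.4
2006_1,mean_therapy_minutes,LTC,10.2
2006_2,mean_therapy_minutes,CCC,121.6
2006_2,mean_therapy_minutes,LTC,19.2
2006_3,mean_therapy_minutes,CCC,117.2
2006_3,mean_therapy_minutes,LTC,22.9
2006_4,mean_therapy_minutes,CCC,119.0
2006_4,mean_therapy_minutes,LTC,22.7
2007_1,mean_therapy_minutes,CCC,114.7
2007_1,mean_therapy_minutes,LTC,24.7
2007_2,mean_therapy_minutes,CCC,120.1
2007_2,mean_therapy_minutes,LTC,24.6
2007_3,mean_therapy_minutes,CCC,118.6
2007_3,mean_therapy_minutes,LTC,25.2
2007_4,mean_therapy_minutes,CCC,121.4
2007_4,mean_therapy_minutes,LTC,25.2
2008_1,mean_therapy_minutes,CCC,119.5
2008_1,mean_therapy_minutes,LTC,25.0
2008_2,mean_therapy_minutes,CCC,122.4
2008_2,mean_therapy_minutes,LTC,26.0
2008_3,mean_therapy_minutes,CCC,117.4
2008_3,mean_therapy_minutes,LTC,27.3
2008_4,mean_therapy_minutes,CCC,124.6
2008_4,mean_therapy_minutes,LTC,27.6
2009_1,mean_therapy_minutes,CCC,127.2
2009_1,mean_therapy_minutes,LTC,28.5
2009_2,mean_therapy_minutes,CCC,128.5
2009_2,mean_therapy_minutes,LTC,31.3
2009_3,mean_therapy_minutes,CCC,122.2
2009_3,mean_therapy_minutes,LTC,33.3
2009_4,mean_therapy_minutes,CCC,123.2
2009_4,mean_therapy_minutes,LTC,35.6
2010_1,mean_therapy_minutes,CCC,127.9
2010_1,mean_therapy_minutes,LTC,38.1
2010_2,mean_therapy_minutes,CCC,133.4
2010_2,mean_therapy_minutes,LTC,40.6
2010_3,mean_therapy_minutes,CCC,130.7
2010_3,mean_therapy_minutes,LTC,41.0
2010_4,mean_therapy_minutes,CCC,137.6
2010_4,mean_therapy_minutes,LTC,41.8
2011_1,mean_therapy_minutes,CCC,142.0
2011_1,mean_therapy_minutes,LTC,42.4
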