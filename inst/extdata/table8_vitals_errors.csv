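quarter,indicator,sector,value
1996_3,height_err,CCC,2.1
1996_3,weight_err,CCC,9.3
1996_3,age_err,CCC,0.0
1996_4,height_err,CCC,1.8
1996_4,weight_err,CCC,11.7
1996_4,age_err,CCC,0.2
1997_1,height_err,CCC,2.4
1997_1,weight_err,CCC,13.3
1997_1,age_err,CCC,0.2
1997_2,height_err,CCC,2.7
1997_2,weight_err,CCC,16.0
1997_2,age_err,CCC,0.3
1997_3,height_err,CCC,2.4
1997_3,weight_err,CCC,19.4
1997_3,age_err,CCC,0.3
1997_4,height_err,CCC,2.4
1997_4,weight_err,CCC,20.6
1997_4,age_err,CCC,0.2
1998_1,height_err,CCC,2.3
1998_1,weight_err,CCC,20.5
1998_1,age_err,CCC,0.2
1998_2,height_err,CCC,2.5
1998_2,weight_err,CCC,20.7
1998_2,age_err,CCC,0.3
1998_3,height_err,CCC,2.5
1998_3,weight_err,CCC,19.5
1998_3,age_err,CCC,0.3
1998_4,height_err,CCC,2.7
1998_4,weight_err,CCC,18.9
1998_4,age_err,CCC,0.3
1999_1,height_err,CCC,3.1
1999_1,weight_err,CCC,16.0
1999_1,age_err,CCC,0.2
1999_2,height_err,CCC,3.0
1999_2,weight_err,CCC,17.0
1999_2,age_err,CCC,0.3
1999_3,height_err,CCC,3.1
1999_3,weight_err,CCC,15.8
1999_3,age_err,CCC,0.3
1999_4,height_err,CCC,3.5
1999_4,weight_err,CCC,13.1
1999_4,age_err,CCC,0.2
2000_1,height_err,CCC,3.6
2000_1,weight_err,CCC,12.4
2000_1,age_err,CCC,0.2
2000_2,height_err,CCC,3.8
2000_2,weight_err,CCC,10.4
2000_2,age_err,CCC,0.2
2000_3,height_err,CCC,3.6
2000_3,weight_err,CCC,10.1
2000_3,age_err,CCC,0.2
2000_4,height_err,CCC,3.9
2000_4,weight_err,CCC,11.2
2000_4,age_err,CCC,0.2
2001_1,height_err,CCC,4.3
2001_1,weight_err,CCC,11.1
2001_1,age_err,CCC,0.2
2001_2,height_err,CCC,4.6
2001_2,weight_err,CCC,10.9
2001_2,age_err,CCC,0.2
2001_3,height_err,CCC,4.9
2001_3,weight_err,CCC,10.1
2001_3,age_err,CCC,0.2
2001_4,height_err,CCC,4.3
2001_4,weight_err,CCC,10.0
2001_4,age_err,CCC,0.2
2002_1,height_err,CCC,3.5
2002_1,weight_err,CCC,10.6
2002_1,age_err,CCC,0.3
2002_2,height_err,CCC,3.2
2002_2,weight_err,CCC,12.0
2002_2,age_err,CCC,0.3
2002_3,height_err,CCC,3.6
2002_3,weight_err,CCC,11.9
2002_3,age_err,CCC,0.3
2002_4,height_err,CCC,3.8
2002_4,weight_err,CCC,11.4
2002_4,age_err,CCC,0.3
2003_1,height_err,CCC,4.2
2003_1,weight_err,CCC,10.7
2003_1,age_err,CCC,0.3
2003_2,height_err,CCC,4.4
2003_2,weight_err,CCC,5.4
2003_2,age_err,CCC,0.3
2003_3,height_err,CCC,4.8
2003_3,weight_err,CCC,5.0
2003_3,age_err,CCC,0.4
2003_4,height_err,CCC,3.6
2003_4,weight_err,CCC,4.5
2003_4,age_err,CCC,0.3
2004_1,height_err,CCC,3.7
2004_1,weight_err,CCC,3.5
2004_1,age_err,CCC,0.3
2004_2,height_err,CCC,3.4
2004_2,weight_err,CCC,3.1
2004_2,age_err,CCC,0.3
2004_3,height_err,CCC,3.4
2004_3,weight_err,CCC,3.6
2004_3,age_err,CCC,0.4
2004_4,height_err,CCC,3.1
2004_4,weight_err,CCC,3.4
2004_4,age_err,CCC,0.3
2005_1,height_err,CCC,2.8
2005_1,weight_err,CCC,3.4
2005_1,age_err,CCC,0.3
2005_2,height_err,CCC,3.5
2005_2,weight_err,CCC,3.6
2005_2,age_err,CCC,0.3
2005_3,height_err,CCC,3.7
2005_3,height_err,LTC,0.3
2005_3,weight_err,CCC,3.9
2005_3,weight_err,LTC,0.1
2005_3,age_err,CCC,0.3
2005_3,age_err,LTC,0.0
2005_4,height_err,CCC,3.7
2005_4,height_err,LTC,0.5
2005_4,weight_err,CCC,4.0
2005_4,weight_err,LTC,0.1
2005_4,age_err,CCC,0.5
2005_4,age_err,LTC,0.0
2006_1,height_err,CCC,4.1
2006_1,height_err,LTC,0.5
2006_1,weight_err,CCC,4.1
2006_1,weight_err,LTC,0.1
2006_1,age_err,CCC,0.4
2006_1,age_err,LTC,0.0
2006_2,height_err,CCC,4.2
2006_2,height_err,LTC,0.5
2006_2,weight_err,CCC,4.7
2006_2,weight_err,LTC,0.1
2006_2,age_err,CCC,0.3
2006_2,age_err,LTC,0.0
2006_3,height_err,CCC,5.0
2006_3,height_err,LTC,0.6
2006_3,weight_err,CCC,4.7
2006_3,weight_err,LTC,0.3
2006_3,age_err,CCC,0.3
2006_3,age_err,LTC,0.0
2006_4,height_err,CCC,4.6
2006_4,height_err,LTC,0.5
2006_4,weight_err,CCC,4.5
2006_4,weight_err,LTC,0.2
2006_4,age_err,CCC,0.2
2006_4,age_err,LTC,0.0
2007_1,height_err,CCC,4.5
2007_1,height_err,LTC,0.5
2007_1,weight_err,CCC,4.3
2007_1,weight_err,LTC,0.2
2007_1,age_err,CCC,0.3
2007_1,age_err,LTC,0.0
2007_2,height_err,CCC,5.3
2007_2,height_err,LTC,0.6
2007_2,weight_err,CCC,4.3
2007_2,weight_err,LTC,0.3
2007_2,age_err,CCC,0.4
2007_2,age_err,LTC,0.0
2007_3,height_err,CCC,5.5
2007_3,height_err,LTC,0.5
2007_3,weight_err,CCC,4.6
2007_3,weight_err,LTC,0.3
2007_3,age_err,CCC,0.3
2007_3,age_err,LTC,0.0
2007_4,height_err,CCC,5.7
2007_4,height_err,LTC,0.6
2007_4,weight_err,CCC,4.9
2007_4,weight_err,LTC,0.4
2007_4,age_err,CCC,0.3
2007_4,age_err,LTC,0.0
2008_1,height_err,CCC,4.8
2008_1,height_err,LTC,0.6
2008_1,weight_err,CCC,4.5
2008_1,weight_err,LTC,0.2
2008_1,age_err,CCC,0.3
2008_1,age_err,LTC,0.0
2008_2,height_err,CCC,4.7
2008_2,height_err,LTC,0.4
2008_2,weight_err,CCC,4.5
2008_2,weight_err,LTC,0.2
2008_2,age_err,CCC,0.3
2008_2,age_err,LTC,0.0
2008_3,height_err,CCC,4.5
2008_3,height_err,LTC,0.3
2008_3,weight_err,CCC,4.3
2008_3,weight_err,LTC,0.2
2008_3,age_err,CCC,0.3
2008_3,age_err,LTC,0.0
2008_4,height_err,CCC,3.7
2008_4,height_err,LTC,0.3
2008_4,weight_err,CCC,3.4
2008_4,weight_err,LTC,0.2
2008_4,age_err,CCC,0.3
2008_4,age_err,LTC,0.0
2009_1,height_err,CCC,3.9
2009_1,height_err,LTC,0.3
2009_1,weight_err,CCC,4.0
2009_1,weight_err,LTC,0.3
2009_1,age_err,CCC,0.3
2009_1,age_err,LTC,0.0
2009_2,height_err,CCC,4.1
2009_2,height_err,LTC,0.4
2009_2,weight_err,CCC,4.2
2009_2,weight_err,LTC,0.2
2009_2,age_err,CCC,0.2
2009_2,age_err,LTC,0.0
2009_3,height_err,CCC,4.3
2009_3,height_err,LTC,0.4
2009_3,weight_err,CCC,3.9
2009_3,weight_err,LTC,0.2
2009_3,age_err,CCC,0.3
2009_3,age_err,LTC,0.0
2009_4,height_err,CCC,3.9
2009_4,height_err,LTC,0.3
2009_4,weight_err,CCC,3.9
2009_4,weight_err,LTC,0.3
2009_4,age_err,CCC,0.3
2009_4,age_err,LTC,0.0
2010_1,height_err,CCC,4.5
2010_1,height_err,LTC,0.3
2010_1,weight_err,CCC,4.4
2010_1,weight_err,LTC,0.3
2010_1,age_err,CCC,0.2
2010_1,age_err,LTC,0.0
2010_2,height_err,CCC,3.9
2010_2,height_err,LTC,0.3
2010_2,weight_err,CCC,4.1
2010_2,weight_err,LTC,0.3
2010_2,age_err,CCC,0.2
2010_2,age_err,LTC,0.0
2010_3,height_err,CCC,4.5
2010_3,height_err,LTC,0.3
2010_3,weight_err,CCC,4.3
2010_3,weight_err,LTC,0.3
2010_3,age_err,CCC,0.2
2010_3,age_err,LTC,0.0
2010_4,height_err,CCC,4.1
2010_4,height_err,LTC,0.3
2010_4,weight_err,CCC,3.9
2010_4,weight_err,LTC,0.3
2010_4,age_err,CCC,0.2
2010_4,age_err,LTC,0.0
2011_1,height_err,CCC,4.1
2011_1,height_err,LTC,0.3
2011_1,weight_err,CCC,4.1
2011_1,weight_err,LTC,0.3
2011_1,age_err,CCC,0.2
2011_1,age_err,LTC,0.0
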