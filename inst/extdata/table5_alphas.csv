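quarter,indicator,sector,value
1996_3,alpha_adl_long_form,CCC,0.91
1996_3,alpha_drs,CCC,0.76
1996_3,alpha_abs,CCC,0.76
1996_4,alpha_adl_long_form,CCC,0.91
1996_4,alpha_drs,CCC,0.76
1996_4,alpha_abs,CCC,0.75
1997_1,alpha_adl_long_form,CCC,0.91
1997_1,alpha_drs,CCC,0.75
1997_1,alpha_abs,CCC,0.76
1997_2,alpha_adl_long_form,CCC,0.92
1997_2,alpha_drs,CCC,0.76
1997_2,alpha_abs,CCC,0.77
1997_3,alpha_adl_long_form,CCC,0.91
1997_3,alpha_drs,CCC,0.77
1997_3,alpha_abs,CCC,0.77
1997_4,alpha_adl_long_form,CCC,0.92
1997_4,alpha_drs,CCC,0.77
1997_4,alpha_abs,CCC,0.77
1998_1,alpha_adl_long_form,CCC,0.91
1998_1,alpha_drs,CCC,0.77
1998_1,alpha_abs,CCC,0.77
1998_2,alpha_adl_long_form,CCC,0.92
1998_2,alpha_drs,CCC,0.76
1998_2,alpha_abs,CCC,0.78
1998_3,alpha_adl_long_form,CCC,0.92
1998_3,alpha_drs,CCC,0.76
1998_3,alpha_abs,CCC,0.78
1998_4,alpha_adl_long_form,CCC,0.92
1998_4,alpha_drs,CCC,0.76
1998_4,alpha_abs,CCC,0.77
1999_1,alpha_adl_long_form,CCC,0.92
1999_1,alpha_drs,CCC,0.76
1999_1,alpha_abs,CCC,0.78
1999_2,alpha_adl_long_form,CCC,0.92
1999_2,alpha_drs,CCC,0.75
1999_2,alpha_abs,CCC,0.78
1999_3,alpha_adl_long_form,CCC,0.92
1999_3,alpha_drs,CCC,0.75
1999_3,alpha_abs,CCC,0.78
1999_4,alpha_adl_long_form,CCC,0.92
1999_4,alpha_drs,CCC,0.75
1999_4,alpha_abs,CCC,0.78
2000_1,alpha_adl_long_form,CCC,0.92
2000_1,alpha_drs,CCC,0.75
2000_1,alpha_abs,CCC,0.79
2000_2,alpha_adl_long_form,CCC,0.92
2000_2,alpha_drs,CCC,0.76
2000_2,alpha_abs,CCC,0.80
2000_3,alpha_adl_long_form,CCC,0.92
2000_3,alpha_drs,CCC,0.75
2000_3,alpha_abs,CCC,0.80
2000_4,alpha_adl_long_form,CCC,0.92
2000_4,alpha_drs,CCC,0.76
2000_4,alpha_abs,CCC,0.80
2001_1,alpha_adl_long_form,CCC,0.92
2001_1,alpha_drs,CCC,0.75
2001_1,alpha_abs,CCC,0.79
2001_2,alpha_adl_long_form,CCC,0.92
2001_2,alpha_drs,CCC,0.75
2001_2,alpha_abs,CCC,0.79
2001_3,alpha_adl_long_form,CCC,0.92
2001_3,alpha_drs,CCC,0.75
2001_3,alpha_abs,CCC,0.78
2001_4,alpha_adl_long_form,CCC,0.92
2001_4,alpha_drs,CCC,0.74
2001_4,alpha_abs,CCC,0.78
2002_1,alpha_adl_long_form,CCC,0.92
2002_1,alpha_drs,CCC,0.74
2002_1,alpha_abs,CCC,0.79
2002_2,alpha_adl_long_form,CCC,0.92
2002_2,alpha_drs,CCC,0.75
2002_2,alpha_abs,CCC,0.79
2002_3,alpha_adl_long_form,CCC,0.92
2002_3,alpha_drs,CCC,0.75
2002_3,alpha_abs,CCC,0.79
2002_4,alpha_adl_long_form,CCC,0.92
2002_4,alpha_drs,CCC,0.75
2002_4,alpha_abs,CCC,0.78
2003_1,alpha_adl_long_form,CCC,0.92
2003_1,alpha_drs,CCC,0.75
2003_1,alpha_abs,CCC,0.79
2003_2,alpha_adl_long_form,CCC,0.92
2003_2,alpha_drs,CCC,0.76
2003_2,alpha_abs,CCC,0.77
2003_3,alpha_adl_long_form,CCC,0.92
2003_3,alpha_drs,CCC,0.77
2003_3,alpha_abs,CCC,0.78
2003_4,alpha_adl_long_form,CCC,0.92
2003_4,alpha_drs,CCC,0.76
2003_4,alpha_abs,CCC,0.77
2004_1,alpha_adl_long_form,CCC,0.92
2004_1,alpha_drs,CCC,0.76
2004_1,alpha_abs,CCC,0.77
2004_2,alpha_adl_long_form,CCC,0.92
2004_2,alpha_drs,CCC,0.75
2004_2,alpha_abs,CCC,0.78
2004_3,alpha_adl_long_form,CCC,0.92
2004_3,alpha_drs,CCC,0.76
2004_3,alpha_abs,CCC,0.77
2004_4,alpha_adl_long_form,CCC,0.92
2004_4,alpha_drs,CCC,0.76
2004_4,alpha_abs,CCC,0.76
2005_1,alpha_adl_long_form,CCC,0.92
2005_1,alpha_drs,CCC,0.76
2005_1,alpha_abs,CCC,0.77
2005_2,alpha_adl_long_form,CCC,0.92
2005_2,alpha_drs,CCC,0.75
2005_2,alpha_abs,CCC,0.77
2005_3,alpha_adl_long_form,CCC,0.92
2005_3,alpha_adl_long_form,LTC,0.92
2005_3,alpha_drs,CCC,0.75
2005_3,alpha_drs,LTC,0.72
2005_3,alpha_abs,CCC,0.78
2005_3,alpha_abs,LTC,0.79
2005_4,alpha_adl_long_form,CCC,0.93
2005_4,alpha_adl_long_form,LTC,0.93
2005_4,alpha_drs,CCC,0.75
2005_4,alpha_drs,LTC,0.70
2005_4,alpha_abs,CCC,0.79
2005_4,alpha_abs,LTC,0.75
2006_1,alpha_adl_long_form,CCC,0.93
2006_1,alpha_adl_long_form,LTC,0.93
2006_1,alpha_drs,CCC,0.77
2006_1,alpha_drs,LTC,0.73
2006_1,alpha_abs,CCC,0.78
2006_1,alpha_abs,LTC,0.75
2006_2,alpha_adl_long_form,CCC,0.93
2006_2,alpha_adl_long_form,LTC,0.93
2006_2,alpha_drs,CCC,0.77
2006_2,alpha_drs,LTC,0.71
2006_2,alpha_abs,CCC,0.79
2006_2,alpha_abs,LTC,0.74
2006_3,alpha_adl_long_form,CCC,0.93
2006_3,alpha_adl_long_form,LTC,0.93
2006_3,alpha_drs,CCC,0.76
2006_3,alpha_drs,LTC,0.71
2006_3,alpha_abs,CCC,0.80
2006_3,alpha_abs,LTC,0.73
2006_4,alpha_adl_long_form,CCC,0.93
2006_4,alpha_adl_long_form,LTC,0.93
2006_4,alpha_drs,CCC,0.76
2006_4,alpha_drs,LTC,0.70
2006_4,alpha_abs,CCC,0.80
2006_4,alpha_abs,LTC,0.72
2007_1,alpha_adl_long_form,CCC,0.92
2007_1,alpha_adl_long_form,LTC,0.93
2007_1,alpha_drs,CCC,0.75
2007_1,alpha_drs,LTC,0.70
2007_1,alpha_abs,CCC,0.80
2007_1,alpha_abs,LTC,0.72
2007_2,alpha_adl_long_form,CCC,0.92
2007_2,alpha_adl_long_form,LTC,0.93
2007_2,alpha_drs,CCC,0.76
2007_2,alpha_drs,LTC,0.70
2007_2,alpha_abs,CCC,0.80
2007_2,alpha_abs,LTC,0.72
2007_3,alpha_adl_long_form,CCC,0.92
2007_3,alpha_adl_long_form,LTC,0.94
2007_3,alpha_drs,CCC,0.76
2007_3,alpha_drs,LTC,0.70
2007_3,alpha_abs,CCC,0.80
2007_3,alpha_abs,LTC,0.72
2007_4,alpha_adl_long_form,CCC,0.92
2007_4,alpha_adl_long_form,LTC,0.94
2007_4,alpha_drs,CCC,0.76
2007_4,alpha_drs,LTC,0.71
2007_4,alpha_abs,CCC,0.80
2007_4,alpha_abs,LTC,0.73
2008_1,alpha_adl_long_form,CCC,0.92
2008_1,alpha_adl_long_form,LTC,0.94
2008_1,alpha_drs,CCC,0.76
2008_1,alpha_drs,LTC,0.71
2008_1,alpha_abs,CCC,0.80
2008_1,alpha_abs,LTC,0.73
2008_2,alpha_adl_long_form,CCC,0.92
2008_2,alpha_adl_long_form,LTC,0.94
2008_2,alpha_drs,CCC,0.75
2008_2,alpha_drs,LTC,0.71
2008_2,alpha_abs,CCC,0.79
2008_2,alpha_abs,LTC,0.73
2008_3,alpha_adl_long_form,CCC,0.92
2008_3,alpha_adl_long_form,LTC,0.94
2008_3,alpha_drs,CCC,0.76
2008_3,alpha_drs,LTC,0.71
2008_3,alpha_abs,CCC,0.80
2008_3,alpha_abs,LTC,0.73
2008_4,alpha_adl_long_form,CCC,0.92
2008_4,alpha_adl_long_form,LTC,0.94
2008_4,alpha_drs,CCC,0.76
2008_4,alpha_drs,LTC,0.72
2008_4,alpha_abs,CCC,0.79
2008_4,alpha_abs,LTC,0.72
2009_1,alpha_adl_long_form,CCC,0.92
2009_1,alpha_adl_long_form,LTC,0.94
2009_1,alpha_drs,CCC,0.75
2009_1,alpha_drs,LTC,0.71
2009_1,alpha_abs,CCC,0.81
2009_1,alpha_abs,LTC,0.72
2009_2,alpha_adl_long_form,CCC,0.92
2009_2,alpha_adl_long_form,LTC,0.94
2009_2,alpha_drs,CCC,0.75
2009_2,alpha_drs,LTC,0.72
2009_2,alpha_abs,CCC,0.80
2009_2,alpha_abs,LTC,0.73
2009_3,alpha_adl_long_form,CCC,0.92
2009_3,alpha_adl_long_form,LTC,0.94
2009_3,alpha_drs,CCC,0.75
2009_3,alpha_drs,LTC,0.72
2009_3,alpha_abs,CCC,0.80
2009_3,alpha_abs,LTC,0.73
2009_4,alpha_adl_long_form,CCC,0.92
2009_4,alpha_adl_long_form,LTC,0.94
2009_4,alpha_drs,CCC,0.75
2009_4,alpha_drs,LTC,0.71
2009_4,alpha_abs,CCC,0.81
2009_4,alpha_abs,LTC,0.73
2010_1,alpha_adl_long_form,CCC,0.92
2010_1,alpha_adl_long_form,LTC,0.94
2010_1,alpha_drs,CCC,0.75
2010_1,alpha_drs,LTC,0.71
2010_1,alpha_abs,CCC,0.79
2010_1,alpha_abs,LTC,0.73
2010_2,alpha_adl_long_form,CCC,0.92
2010_2,alpha_adl_long_form,LTC,0.94
2010_2,alpha_drs,CCC,0.74
2010_2,alpha_drs,LTC,0.71
2010_2,alpha_abs,CCC,0.80
2010_2,alpha_abs,LTC,0.74
2010_3,alpha_adl_long_form,CCC,0.92
2010_3,alpha_adl_long_form,LTC,0.94
2010_3,alpha_drs,CCC,0.75
2010_3,alpha_drs,LTC,0.71
2010_3,alpha_abs,CCC,0.80
2010_3,alpha_abs,LTC,0.74
2010_4,alpha_adl_long_form,CCC,0.93
2010_4,alpha_adl_long_form,LTC,0.94
2010_4,alpha_drs,CCC,0.75
2010_4,alpha_drs,LTC,0.71
2010_4,alpha_abs,CCC,0.79
2010_4,alpha_abs,LTC,0.73
2011_1,alpha_adl_long_form,CCC,0.92
2011_1,alpha_adl_long_form,LTC,0.94
2011_1,alpha_drs,CCC,0.73
2011_1,alpha_drs,LTC,0.71
2011_1,alpha_abs,CCC,0.79
2011_1,alpha_abs,LTC,0.73
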