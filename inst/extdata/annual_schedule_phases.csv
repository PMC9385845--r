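individual_id,data_type,phase,area,first_signal,last_signal,start_truncated,end_truncated
39369,Argos,wintering,FR: Nouvelle-Aquitaine,,2003-03-08,TRUE,FALSE
39369,Argos,spring_migration,,2003-03-11,2003-03-20,FALSE,FALSE
39369,Argos,breeding,DE: Bavaria,2003-08-17,2003-08-17,FALSE,TRUE
90094,Argos,wintering,FR: Nouvelle-Aquitaine,,2009-03-11,TRUE,FALSE
90094,Argos,spring_migration,,2009-03-18,2009-04-03,FALSE,FALSE
90094,Argos,breeding,DE: Lower Saxony,2009-04-15,,FALSE,TRUE
90094,Argos,wintering,DE: Lower Saxony,,2010-01-07,TRUE,TRUE
90097,Argos,wintering,FR: Nouvelle-Aquitaine,,2009-03-13,TRUE,FALSE
90097,Argos,spring_migration,,2009-03-14,2009-04-03,FALSE,FALSE
90097,Argos,breeding,DE: Bavaria,2009-04-07,2009-09-15,FALSE,TRUE
90099,Argos,wintering,PO: Lisbon,,2009-03-12,TRUE,FALSE
90099,Argos,spring_migration,,2009-03-13,2009-05-13,FALSE,FALSE
90099,Argos,breeding,CH,2009-05-14,,FALSE,TRUE
90099,Argos,wintering,CH/DE: Baden-Wurttemberg,,,TRUE,TRUE
90099,Argos,breeding,CH,,2010-09-27,TRUE,FALSE
90099,Argos,autumn_migration,,2010-10-11,2010-10-23,FALSE,FALSE
90099,Argos,wintering,FR: Nouvelle-Aquitaine,2010-10-30,2011-03-19,FALSE,FALSE
90099,Argos,spring_migration,,2011-03-20,2011-03-23,FALSE,FALSE
90099,Argos,breeding,CH,2011-03-25,,FALSE,TRUE
90099,Argos,wintering,CH,,2011-10-11,TRUE,TRUE
104633,Argos,wintering,FR: Nouvelle-Aquitaine,,2011-03-16,TRUE,FALSE
104633,Argos,spring_migration,,2011-03-18,2011-04-11,FALSE,FALSE
104633,Argos,breeding,DE: Baden-Wurttemberg,2011-04-13,2011-04-18,FALSE,TRUE
104638,Argos,wintering,FR: Nouvelle-Aquitaine,,2011-03-21,TRUE,FALSE
104638,Argos,spring_migration,,2011-03-22,2011-04-20,FALSE,FALSE
104638,Argos,breeding,DE: North Rhine-Westphalia,2011-04-21,2011-07-20,FALSE,TRUE
104639,Argos,wintering,FR: Nouvelle-Aquitaine,,2011-03-17,TRUE,FALSE
104639,Argos,spring_migration,,2011-03-20,2011-03-26,FALSE,FALSE
104639,Argos,breeding,DE: Rhineland-Palatinate,2011-03-31,2011-09-04,FALSE,TRUE
104640,Argos,wintering,FR: Nouvelle-Aquitaine,,2011-03-21,TRUE,FALSE
104640,Argos,spring_migration,,2011-03-23,2011-05-28,FALSE,TRUE
113891,Argos,wintering,FR: Nouvelle-Aquitaine; Occitanie,,2012-02-21,TRUE,FALSE
113891,Argos,spring_migration,,2012-02-25,2012-03-28,FALSE,FALSE
113891,Argos,breeding,DE: Bavaria,2012-03-30,2012-10-17,FALSE,FALSE
113891,Argos,autumn_migration,,2012-10-19,2012-11-05,FALSE,FALSE
113891,Argos,wintering,FR: Nouvelle-Aquitaine,2012-11-10,2013-03-09,FALSE,FALSE
113891,Argos,spring_migration,,2013-03-09,2013-04-03,FALSE,FALSE
113891,Argos,breeding,DE: Bavaria,2013-04-05,2013-07-11,FALSE,TRUE
123147,Argos,wintering,FR: Nouvelle-Aquitaine,,2013-03-07,TRUE,FALSE
123147,Argos,spring_migration,,2013-03-08,2013-04-13,FALSE,FALSE
123147,Argos,breeding,DE: Bavaria,2013-04-14,2013-10-18,FALSE,FALSE
123147,Argos,autumn_migration,,2013-10-25,2013-10-25,FALSE,TRUE
123147,Argos,wintering,FR: Nouvelle-Aquitaine,2013-12-02,2014-03-02,FALSE,TRUE
133559,Argos,wintering,FR: Nouvelle-Aquitaine,,2014-03-06,TRUE,FALSE
133559,Argos,spring_migration,,2014-03-08,2014-03-18,FALSE,FALSE
133559,Argos,breeding,DE: Thuringia,2014-03-20,2014-05-07,FALSE,TRUE
141869,Argos,wintering,FR: Nouvelle-Aquitaine; Occitanie,,2015-03-17,TRUE,FALSE
141869,Argos,spring_migration,,2015-03-19,2015-04-07,FALSE,FALSE
141869,Argos,breeding,DE: Baden-Wurttemberg,2015-04-09,2015-09-26,FALSE,FALSE
141869,Argos,autumn_migration,,2015-09-29,2015-10-20,FALSE,FALSE
141869,Argos,wintering,FR: Nouvelle-Aquitaine; Occitanie,2015-10-22,2016-01-28,FALSE,TRUE
180777,GPS,breeding,DE: Hesse,2018-06-13,,TRUE,TRUE
180777,GPS,wintering,DE: Hesse,,,TRUE,TRUE
180777,GPS,breeding,DE: Hesse,,2019-10-21,TRUE,FALSE
180777,GPS,autumn_migration,,2019-10-21,2019-11-21,FALSE,FALSE
180777,GPS,wintering,FR: Grand-Est,2019-11-21,2020-02-12,FALSE,TRUE
180784,GPS,breeding,DE: Hesse,2019-05-03,2019-11-16,TRUE,FALSE
180784,GPS,autumn_migration,,2019-11-16,2019-12-02,FALSE,FALSE
180784,GPS,wintering,FR: Grand-Est; Bourgogne-Franche-Comte,2019-12-02,2020-03-27,FALSE,FALSE
180784,GPS,spring_migration,,2020-03-28,2020-04-01,FALSE,FALSE
180784,GPS,breeding,DE: Hesse,2020-04-01,,FALSE,TRUE
180784,GPS,wintering,DE: Hesse,,,TRUE,TRUE
180784,GPS,breeding,DE: Hesse,,2021-05-21,TRUE,TRUE
191391,GPS,breeding,DE: Hesse,2019-06-14,2019-11-14,TRUE,FALSE
191391,GPS,autumn_migration,,2019-11-14,2019-11-14,FALSE,FALSE
191391,GPS,wintering,DE: Hesse,2019-11-14,2020-03-28,FALSE,FALSE
191391,GPS,spring_migration,,2020-03-28,2020-03-28,FALSE,FALSE
191391,GPS,breeding,DE: Hesse,2020-03-28,,FALSE,TRUE
191391,GPS,wintering,DE: Hesse,,,TRUE,TRUE
191391,GPS,breeding,DE: Hesse,,2021-05-21,TRUE,TRUE
190758,GPS,breeding,DE: Hesse,2019-06-18,2019-10-23,TRUE,FALSE
190758,GPS,autumn_migration,,2019-10-23,2019-11-29,FALSE,FALSE
190758,GPS,wintering,FR: Grand-Est,2019-11-29,2020-04-03,FALSE,FALSE
190758,GPS,spring_migration,,2020-04-03,2020-04-24,FALSE,FALSE
190758,GPS,breeding,DE: Hesse,2020-04-24,2020-10-31,FALSE,TRUE
190213,GPS,breeding,DE: Hesse,2019-07-30,2019-10-20,TRUE,FALSE
190213,GPS,autumn_migration,,2019-10-20,2019-11-15,FALSE,FALSE
190213,GPS,wintering,FR: Grand-Est,2019-11-15,2020-03-23,FALSE,FALSE
190213,GPS,spring_migration,,2020-03-24,2020-04-01,FALSE,FALSE
190213,GPS,breeding,DE: Hesse,2020-04-01,,FALSE,TRUE
190213,GPS,wintering,DE: Hesse,,,TRUE,TRUE
190213,GPS,breeding,DE: Hesse,,2021-05-31,TRUE,TRUE
190763,GPS,breeding,DE: Hesse,2020-06-12,2020-11-17,TRUE,FALSE
190763,GPS,autumn_migration,,2020-11-17,2020-11-17,FALSE,FALSE
190763,GPS,wintering,DE: Hesse,2020-11-17,2021-03-09,FALSE,TRUE
190764,GPS,breeding,DE: Hesse,2020-06-16,2020-11-06,TRUE,FALSE
190764,GPS,autumn_migration,,2020-11-06,2020-11-07,FALSE,FALSE
190764,GPS,wintering,DE: Hesse,2020-11-07,2021-02-17,FALSE,FALSE
190764,GPS,spring_migration,,2021-02-17,2021-02-18,FALSE,FALSE
190764,GPS,breeding,DE: Hesse,2021-02-18,2021-05-31,FALSE,TRUE
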