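sample_id	NCP
S001_2016_0p2um	-1.44494029351527
S002_2016_0p2um	-1.15543103039267
S003_2016_0p2um	-2.23778205735304
S004_2016_0p2um	0.0928098671952328
S005_2016_0p2um	-0.182070407482165
S006_2016_0p2um	-0.00142568231056317
S007_2016_0p2um	2.32173048511501
S008_2016_0p2um	0.328947969089613
S009_2016_0p2um	0.87494376635508
S010_2016_0p2um	0.962588295493317
S011_2016_3p0um	-0.578193858707695
S012_2016_3p0um	-0.750168164666526
S013_2016_3p0um	-1.27187931927081
S014_2016_3p0um	0.0745687340790525
S015_2016_3p0um	0.518954071996616
S016_2016_3p0um	0.220016029000421
S017_2016_3p0um	-2.0822128728581
S018_2016_3p0um	0.101246441129881
S019_2016_3p0um	0.90763182128191
S020_2016_3p0um	0.140067306240082
S021_2017_0p2um	-0.597284499914939
S022_2017_0p2um	0.699245859504023
S023_2017_0p2um	-1.7673609873916
S024_2017_0p2um	0.312472095138573
S025_2017_0p2um	0.167250552294986
S026_2017_0p2um	0.328493711910002
S027_2017_0p2um	0.768356781475831
S028_2017_0p2um	-0.958394392247017
S029_2017_0p2um	0.224819313792909
S030_2017_0p2um	0.912359846449634
S031_2017_3p0um	-0.58627088637988
S032_2017_3p0um	0.523605329465105
S033_2017_3p0um	-0.606840120244968
S034_2017_3p0um	0.294864940536652
S035_2017_3p0um	1.47403522297095
S036_2017_3p0um	-0.883188293639505
S037_2017_3p0um	0.691223293852061
S038_2017_3p0um	-1.07909807357882
S039_2017_3p0um	0.901192383772296
S040_2017_3p0um	1.13036347558812
S041_2019_0p2um	0.0138135706813457
S042_2019_0p2um	0.179793315785962
S043_2019_0p2um	-1.49709905662203
S044_2019_0p2um	-0.0703682146201041
S045_2019_0p2um	0.666386395451917
S046_2019_0p2um	0.456665579194224
S047_2019_0p2um	0.0202966218948805
S048_2019_0p2um	0.93936568003131
S049_2019_0p2um	1.04282901895296
S050_2019_0p2um	-0.337772890415913
S051_2019_3p0um	-0.0190923186150173
S052_2019_3p0um	-0.975680370859192
S053_2019_3p0um	-0.733558079493719
S054_2019_3p0um	1.19657822750305
S055_2019_3p0um	0.60444744709754
S056_2019_3p0um	0.562037883480682
S057_2019_3p0um	-1.00162142811809
S058_2019_3p0um	0.654142760057638
S059_2019_3p0um	0.442206720575274
S060_2019_3p0um	-0.93261751573651
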