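year	month	latitude	depth	size_fraction	sample_id	depth_bin	salinity	chlorophyll	region
2016	April	24.0540416057286	15	0.2	S001_2016_0p2um	0-15	36.0383144737629	0.0124970865059264	NPSG
2016	April	26.0267977638006	15	0.2	S002_2016_0p2um	0-15	35.7626404724591	0.0202270360857976	NPSG
2016	April	27.9320222850549	15	0.2	S003_2016_0p2um	0-15	35.4867104244238	0.0271795659540334	NPSG
2016	April	29.9306305899675	15	0.2	S004_2016_0p2um	0-15	35.1853749577023	0.0512786588121685	NPSG
2016	April	31.9787674380434	15	0.2	S005_2016_0p2um	0-15	34.8601697866655	0.0735706234948572	NPSG
2016	April	33.8891741445439	15	0.2	S006_2016_0p2um	0-15	34.5843486736697	0.134149709648367	STZ
2016	April	35.80234334382	15	0.2	S007_2016_0p2um	0-15	34.3055775207231	0.220256343918376	NTZ
2016	April	38.1041766796296	15	0.2	S008_2016_0p2um	0-15	33.9299855434426	0.408119045661723	NTZ
2016	April	40.1006979795311	15	0.2	S009_2016_0p2um	0-15	33.6269954149873	0.631652439523298	NTZ
2016	April	41.9474434325476	15	0.2	S010_2016_0p2um	0-15	33.3107563123625	0.976207903824471	NTZ
2016	April	24.1908993833468	15	3	S011_2016_3p0um	0-15	36.0164607593796	0.0123312601710114	NPSG
2016	April	25.9653880388895	15	3	S012_2016_3p0um	0-15	35.7790931337049	0.0178518537437754	NPSG
2016	April	28.0321922530626	15	3	S013_2016_3p0um	0-15	35.5021663515483	0.0261031444163944	NPSG
2016	April	29.918610608395	15	3	S014_2016_3p0um	0-15	35.1620311371383	0.0440044595462598	NPSG
2016	April	32.0970661123743	15	3	S015_2016_3p0um	0-15	34.8486747365154	0.0805445177665523	NPSG
2016	April	34.2068486857327	15	3	S016_2016_3p0um	0-15	34.5367885228166	0.144021513002676	STZ
2016	April	35.9487272789126	15	3	S017_2016_3p0um	0-15	34.2860037598612	0.17973704083053	NTZ
2016	April	38.1417196715032	15	3	S018_2016_3p0um	0-15	33.9189408263483	0.375626010558435	NTZ
2016	April	40.1446602403835	15	3	S019_2016_3p0um	0-15	33.6476016592638	0.562264243955069	NTZ
2016	April	42.0950359735775	15	3	S020_2016_3p0um	0-15	33.3593577569132	0.926621003841339	NTZ
2017	May	24.0300766810324	15	0.2	S021_2017_0p2um	0-15	36.030867004423	0.0108352095040322	NPSG
2017	May	26.0693279741978	15	0.2	S022_2017_0p2um	0-15	35.7297573992058	0.0162765593936889	NPSG
2017	May	28.3119978930183	15	0.2	S023_2017_0p2um	0-15	35.3587652555853	0.0287652292560349	NPSG
2017	May	29.8656803848931	15	0.2	S024_2017_0p2um	0-15	35.1856861627872	0.048442117413088	NPSG
2017	May	32.0304223444728	15	0.2	S025_2017_0p2um	0-15	34.8404282328313	0.0785343706809296	NPSG
2017	May	33.8599505793335	15	0.2	S026_2017_0p2um	0-15	34.5999160612203	0.12342082634974	STZ
2017	May	35.909460941427	15	0.2	S027_2017_0p2um	0-15	34.2898555280314	0.242146204502644	NTZ
2017	May	37.865292455802	15	0.2	S028_2017_0p2um	0-15	33.9815908511389	0.398853471340741	NTZ
2017	May	39.9761801151034	15	0.2	S029_2017_0p2um	0-15	33.6736061651458	0.664134297587839	NTZ
2017	May	41.9293314323775	15	0.2	S030_2017_0p2um	0-15	33.3715322130067	0.996008098516368	NTZ
2017	May	24.07042628025	15	3	S031_2017_3p0um	0-15	36.064269735648	0.0123017807765839	NPSG
2017	May	26.1434991186492	15	3	S032_2017_3p0um	0-15	35.7393314192256	0.0156430641047999	NPSG
2017	May	27.8887350714069	15	3	S033_2017_3p0um	0-15	35.4820884148882	0.0277306104096192	NPSG
2017	May	29.9645083812088	15	3	S034_2017_3p0um	0-15	35.1932928350442	0.0643397227876913	NPSG
2017	May	32.1087932222354	15	3	S035_2017_3p0um	0-15	34.8460134069199	0.0856722511074427	NPSG
2017	May	33.9841303743777	15	3	S036_2017_3p0um	0-15	34.5717463225388	0.129148554541943	STZ
2017	May	36.1707293959365	15	3	S037_2017_3p0um	0-15	34.2497965469596	0.229952286184661	NTZ
2017	May	37.885659133149	15	3	S038_2017_3p0um	0-15	33.9820530878629	0.342394118643826	NTZ
2017	May	39.9725177615205	15	3	S039_2017_3p0um	0-15	33.6735752051984	0.552437621657048	NTZ
2017	May	42.0292397739543	15	3	S040_2017_3p0um	0-15	33.3654197826973	0.894963922672524	NTZ
2019	June	24.0147874302106	15	0.2	S041_2019_0p2um	0-15	36.1085558914315	0.0106293803102395	NPSG
2019	June	25.810094988121	15	0.2	S042_2019_0p2um	0-15	35.7987869442477	0.0188168528704322	NPSG
2019	June	27.9432299249975	15	0.2	S043_2019_0p2um	0-15	35.4654802614109	0.0269105074739492	NPSG
2019	June	30.1370401206882	15	0.2	S044_2019_0p2um	0-15	35.1083514116038	0.047030756620055	NPSG
2019	June	32.0958134639044	15	0.2	S045_2019_0p2um	0-15	34.8278643036192	0.0904643446054586	NPSG
2019	June	33.9702890140586	15	0.2	S046_2019_0p2um	0-15	34.5776822450189	0.128586455705727	STZ
2019	June	35.8392325058814	15	0.2	S047_2019_0p2um	0-15	34.2558218675375	0.217481722136311	NTZ
2019	June	37.9967747535245	15	0.2	S048_2019_0p2um	0-15	33.9776218394323	0.340948672262366	NTZ
2019	June	39.9105560029513	15	0.2	S049_2019_0p2um	0-15	33.6637339495428	0.568862502982232	NTZ
2019	June	42.015659155262	15	0.2	S050_2019_0p2um	0-15	33.3768426417069	0.939857569544018	NTZ
2019	June	24.0822312058715	15	3	S051_2019_3p0um	0-15	36.0342495960034	0.0106004221542076	NPSG
2019	June	25.8874065130267	15	3	S052_2019_3p0um	0-15	35.7821716565626	0.0158501550326641	NPSG
2019	June	27.9892089329011	15	3	S053_2019_3p0um	0-15	35.4788220870418	0.0291820285302878	NPSG
2019	June	30.0031856199071	15	3	S054_2019_3p0um	0-15	35.1467362854805	0.0549302904487346	NPSG
2019	June	31.9926967878317	15	3	S055_2019_3p0um	0-15	34.8310218097643	0.0766296639726691	NPSG
2019	June	34.0645211515379	15	3	S056_2019_3p0um	0-15	34.5210036496427	0.144863540145884	STZ
2019	June	36.0518598572111	15	3	S057_2019_3p0um	0-15	34.2610362927322	0.18761832358151	NTZ
2019	June	38.0363812791418	15	3	S058_2019_3p0um	0-15	33.985879506955	0.387978033774484	NTZ
2019	June	39.9815911387801	15	3	S059_2019_3p0um	0-15	33.6806980781291	0.725813013488297	NTZ
2019	June	42.0690933820869	15	3	S060_2019_3p0um	0-15	33.3710792831198	0.9150690072579	NTZ
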