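sample	population	latitude	longitude	region
YNLH_1	YNLH	24°51'	98°18'	southwest
YNNE_1	YNNE	23°03'	101°02'	southwest
SCNJ_1	SCNJ	29°40'	104°57'	southwest
GXBS_1	GXBS	23°23'	105°49'	south
GZLD_1	GZLD	25°25'	106°45'	south
GZCJ_1	GZCJ	25°44'	108°54'	south
GXLZ_1	GXLZ	25°45'	109°36'	south
HNBT_1	HNBT	18°38'	109°46'	south
GDQY_1	GDQY	23°40'	113°03'	south
FJXM_1	FJXM	24°25'	118°24'	south
HBWX_1	HBWX	29°50'	115°33'	central
HNXY_1	HNXY	32°06'	114°01'	central
JSSN_1	JSSN	33°52'	117°59'	central
AHWH_1	AHWH	33°09'	117°51'	central
SDHZ_1	SDHZ	34°46'	116°06'	central
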