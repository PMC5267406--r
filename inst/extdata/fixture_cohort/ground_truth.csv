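"patient_id","z0","z48","drift","p_death","outcome01"
"P0001",0.981969411350441,0.579069792992363,0.397100381641922,0.723678640945283,0
"P0002",0.468715040036087,-1.87493746067513,-1.54365250071121,0.396948262237555,0
"P0003",-0.107971332216443,0.27382896613826,-0.118199701645296,0.45839151283578,1
"P0004",-1.71287816897121,-1.8281802842216,0.684697884749606,0.537604750579319,0
"P0005",1.15809845503933,-1.69762386277728,-2.0557223178166,0.469357145953232,0
"P0006",-0.207645154562121,0.182930839671325,-0.109424005766554,0.722686933995111,1
"P0007",0.534647146132313,-1.70514649905219,-1.43979364518451,0.422255309159822,0
"P0008",-0.12703471920428,-1.25236969193243,-0.325334972728149,0.429072069435874,0
"P0009",-1.22487541446907,-2.53015630236178,-0.505280887892707,0.222028593039974,0
"P0010",-1.12135130216029,0.582897736927374,1.20424903908767,0.421577889109123,1
"P0011",-1.6719250240929,-2.97090392259745,-0.498978898504543,0.166814721876338,0
"P0012",0.468917929783841,1.35851341148992,0.389595481706078,0.633808226593466,1
"P0013",-0.667810093522374,0.169521781341364,0.337331874863737,0.692764388803934,1
"P0014",0.293021605112214,0.303760055061989,-0.489261550050225,0.492111575627241,1
"P0015",-4.77428582255762,-6.14505688324979,-0.570771060692166,0.0508755722217274,0
"P0016",-1.64811075118461,-2.01974668700832,0.428364064176291,0.518579093548382,0
"P0017",-2.42993873527463,-2.80240057248077,-0.872461837206139,0.231204086256744,1
"P0018",0.454214351568125,0.949523338209383,-0.00469101335874222,0.584113554139535,1
"P0019",-1.60610724067137,-1.91073209169114,0.495375148980223,0.257588361981496,0
"P0020",-2.01147132874967,0.461347350619777,1.97281867936945,0.34431793635443,1
"P0021",1.13997663396662,-0.856885489986017,-1.19686212395264,0.572536459865603,0
"P0022",0.315702951821837,0.946141432938676,0.130438481116839,0.573571716332132,1
"P0023",1.04268610000034,1.87174574018634,0.329059640185992,0.726579276018049,1
"P0024",-0.21298249662589,0.955175804993109,0.668158301618999,0.535527609239507,1
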