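"patch_id","name","R","G","B","X","Y","Z"
1,"dark skin",0.45098,0.321569,0.266667,0.111313,0.100975,0.068304
2,"light skin",0.760784,0.588235,0.509804,0.371847,0.348956,0.258917
3,"blue sky",0.384314,0.478431,0.615686,0.180805,0.189492,0.345966
4,"foliage",0.341176,0.423529,0.262745,0.10306,0.131564,0.073056
5,"blue flower",0.521569,0.501961,0.694118,0.253259,0.235988,0.448072
6,"bluish green",0.403922,0.741176,0.666667,0.310438,0.421786,0.445278
7,"orange",0.839216,0.494118,0.172549,0.356502,0.294035,0.061804
8,"purplish blue",0.313725,0.356863,0.65098,0.139301,0.119399,0.376396
9,"moderate red",0.756863,0.352941,0.388235,0.279026,0.195537,0.141068
10,"purple",0.368627,0.235294,0.423529,0.089383,0.066943,0.150057
11,"yellow green",0.615686,0.737255,0.25098,0.328136,0.435046,0.11518
12,"orange yellow",0.878431,0.639216,0.180392,0.44334,0.422426,0.084029
13,"blue",0.219608,0.239216,0.588235,0.088029,0.063796,0.296157
14,"green",0.27451,0.580392,0.286275,0.143175,0.229618,0.099796
15,"red",0.686275,0.211765,0.235294,0.19816,0.120814,0.055626
16,"yellow",0.905882,0.780392,0.121569,0.536288,0.579378,0.096544
17,"magenta",0.733333,0.337255,0.584314,0.292468,0.193927,0.306308
18,"cyan",0.031373,0.521569,0.631373,0.149179,0.193979,0.366692
19,"white 9.5",0.952941,0.952941,0.94902,0.850371,0.895667,0.967953
20,"neutral 8",0.784314,0.784314,0.784314,0.548973,0.57758,0.628887
21,"neutral 6.5",0.627451,0.627451,0.627451,0.334121,0.351533,0.382759
22,"neutral 5",0.478431,0.478431,0.478431,0.184978,0.194618,0.211906
23,"neutral 3.5",0.333333,0.333333,0.333333,0.086342,0.090842,0.098911
24,"black 2",0.203922,0.203922,0.203922,0.032639,0.03434,0.03739
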