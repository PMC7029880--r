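unit,sp001,sp002,sp003,sp004,sp005,sp006,sp007,sp008,sp009,sp010,sp011,sp012
u001,0,0,0,0,1,0,0,0,0,1,0,0
u002,0,0,0,0,0,0,0,0,0,0,0,0
u003,0,0,1,0,0,0,0,0,0,0,0,0
u004,0,0,1,0,0,1,0,1,0,0,0,0
u005,0,0,0,0,0,0,0,0,0,0,0,0
u006,1,0,0,0,0,1,0,0,0,0,0,0
u007,0,0,0,1,0,1,1,0,0,0,1,0
u008,0,0,0,0,0,1,0,1,0,0,0,1
u009,0,0,0,0,0,0,0,0,0,1,0,0
u010,0,0,0,0,0,0,0,0,0,0,0,1
u011,0,0,0,0,1,0,0,0,1,0,0,0
u012,0,0,0,0,0,0,0,0,0,0,0,0
u013,0,0,1,0,0,0,0,0,0,0,0,0
u014,0,0,0,0,0,0,0,0,0,0,0,0
u015,0,0,0,0,0,0,0,0,1,1,0,0
u016,1,0,0,0,0,0,0,0,0,0,0,0
u017,0,0,0,0,1,0,0,0,0,0,0,0
u018,1,0,0,0,1,0,0,1,0,0,0,0
u019,0,0,0,0,0,0,0,0,0,0,0,0
u020,0,0,0,0,0,1,0,0,0,0,0,1
u021,0,0,0,0,1,0,0,0,0,0,0,0
u022,0,0,0,0,0,0,0,1,0,0,0,0
u023,1,0,0,0,1,0,0,0,1,0,0,0
u024,1,0,0,1,0,1,0,0,0,0,0,0
u025,1,0,1,1,0,1,1,0,0,0,1,1
u026,0,1,0,0,0,0,0,0,0,1,0,1
u027,0,0,0,0,1,0,0,1,0,0,0,0
u028,0,0,1,0,0,0,0,0,0,0,0,0
u029,0,0,0,0,0,1,0,0,0,1,1,0
u030,0,0,0,0,0,0,0,0,0,0,0,0
u031,0,0,0,0,0,0,0,0,0,0,0,0
u032,0,0,0,1,0,0,1,0,0,0,0,1
u033,1,1,1,0,0,0,0,0,0,0,0,0
u034,0,0,1,0,1,0,0,0,1,0,0,0
u035,0,1,0,0,0,0,1,0,0,1,0,0
u036,0,0,0,1,0,0,0,0,0,1,0,0
u037,0,0,0,0,0,0,0,0,0,0,0,1
u038,1,0,0,0,0,0,0,1,0,1,0,0
u039,1,0,1,0,0,0,0,1,0,1,1,0
u040,0,0,0,0,1,0,0,0,1,0,0,0
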