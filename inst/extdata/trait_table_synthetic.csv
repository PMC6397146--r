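taxon,sensitivity,indicator_weight,guild
ACHMIN,1.0,2,low_profile
AMPPED,3.4,2,low_profile
GOMPAR,4.2,1,high_profile
NAVLAN,3.8,2,motile
GOMOLI,2.0,1,high_profile
MERCIR,1.6,1,low_profile
RHOABB,2.4,1,low_profile
ENCMIN,1.8,2,high_profile
SURCRU,2.6,1,motile
COCEUG,3.0,2,low_profile
NAVCRY,3.2,2,motile
CALBAC,3.6,1,motile
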