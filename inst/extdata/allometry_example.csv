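taxon_std,b0,b1
Ash,-2.01,2.43
Basswood,-2.48,2.45
Beech,-2.07,2.44
Birch,-2.27,2.45
Black gum/sweet gum,-2.47,2.45
Cedar/juniper,-2.03,2.26
Cherry,-2.48,2.48
Dogwood,-2.48,2.48
Elm,-2.20,2.44
Fir,-2.54,2.43
Hemlock,-2.54,2.44
Hickory,-2.01,2.43
Ironwood,-2.48,2.48
Maple,-1.99,2.38
Oak,-2.03,2.45
Pine,-2.54,2.43
Poplar/tulip poplar,-2.27,2.42
Spruce,-2.58,2.41
Tamarack,-2.54,2.43
Walnut,-2.01,2.43
Other hardwood,-2.48,2.48
Unknown,-2.48,2.48
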