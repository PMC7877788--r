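vernacular,taxon_std
W. Oak,Oak
B. Oak,Oak
Bur Oak,Oak
Oak,Oak
Sug. Maple,Maple
S. Maple,Maple
Maple,Maple
Wh. Pine,Pine
N. Pine,Pine
Pine,Pine
Hemlock,Hemlock
Beech,Beech
Wh. Birch,Birch
Y. Birch,Birch
Birch,Birch
Lynn,Basswood
Basswood,Basswood
Elm,Elm
Wh. Ash,Ash
Ash,Ash
Tamarack,Tamarack
Larch,Tamarack
Cedar,Cedar/juniper
Juniper,Cedar/juniper
Spruce,Spruce
Balsam,Fir
Fir,Fir
Hickory,Hickory
Walnut,Walnut
Butternut,Walnut
Cherry,Cherry
Dogwood,Dogwood
Ironwood,Ironwood
Hornbeam,Ironwood
Aspen,Poplar/tulip poplar
Poplar,Poplar/tulip poplar
Tulip,Poplar/tulip poplar
Gum,Black gum/sweet gum
Black Gum,Black gum/sweet gum
Box Elder,Other hardwood
Locust,Other hardwood
Sycamore,Other hardwood
no tree,No tree
water,Water
Lake,Water
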