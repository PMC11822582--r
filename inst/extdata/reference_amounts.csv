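category_code,group,reference_amount,unit,is_main_dish_default,description
C1,breakfast_cereals,30,g,FALSE,breakfast cereal - puffed / low density
C2,breakfast_cereals,40,g,FALSE,breakfast cereal - flaked
C3,breakfast_cereals,55,g,FALSE,breakfast cereal - granola / dense
C4,breakfast_cereals,55,g,FALSE,hot cereal (as prepared basis)
B1,beverages,355,mL,FALSE,carbonated and soft drinks
J11,beverages,250,mL,FALSE,fruit juices and nectars
D12,yogurts,175,g,FALSE,yogurt
D15,yogurts,200,g,FALSE,drinkable yogurt / kefir
starter,restaurant,140,g,FALSE,restaurant starter or appetizer
entree,restaurant,250,g,TRUE,restaurant entree / main dish
side,restaurant,85,g,FALSE,restaurant side
dessert,restaurant,125,g,FALSE,restaurant dessert
beverage,restaurant,355,mL,FALSE,restaurant beverage
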