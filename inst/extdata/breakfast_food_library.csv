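food_id,name,energy_kcal_per_100g,carb_g,simple_sugar_g,fat_g,mufa_g,sfa_g,protein_g,calcium_mg_per_100g,groups,is_beverage,is_energy_beverage
white_bread,White bread,265,49,5,3.2,0.6,0.7,9,25,cereal,FALSE,FALSE
wholegrain_bread,Wholegrain bread,247,41,6,3.4,0.8,0.8,13,30,cereal,FALSE,FALSE
rusk_toast,Rusk toast,407,72,8,7,2.5,1.5,11,25,cereal,FALSE,FALSE
oat_flakes,Oat flakes,379,67,1,6.5,2.2,1.2,13,52,cereal,FALSE,FALSE
sugary_breakfast_cereal,Sugar-coated breakfast cereal,387,84,35,2.5,0.8,0.6,6,20,cereal;sugar_rich,FALSE,FALSE
maria_biscuits,Maria biscuits,436,75,22,12,4.5,5.5,7,25,cereal;sugar_rich,FALSE,FALSE
croissant,Croissant,406,45,11,21,8,12,8,37,cereal;sugar_rich,FALSE,FALSE
chocolate_pastry,Chocolate pastry,450,55,28,22,8,11,6,40,sugar_rich,FALSE,FALSE
cocoa_powder,Soluble cocoa powder,377,81,75,3.5,1.1,2,5,35,sugar_rich,FALSE,FALSE
strawberry_jam,Strawberry jam,278,69,49,0.1,0.01,0.01,0.4,20,sugar_rich,FALSE,FALSE
honey,Honey,304,82,82,0,0,0,0.3,6,sugar_rich,FALSE,FALSE
whole_milk,Whole milk,61,4.7,4.7,3.3,0.8,1.9,3.2,113,dairy,TRUE,TRUE
semiskimmed_milk,Semi-skimmed milk,46,4.8,4.8,1.6,0.4,1,3.3,120,dairy,TRUE,TRUE
milk_with_cocoa,Milk with cocoa,78,10.5,9.8,2.8,0.7,1.7,3.4,110,dairy;sugar_rich,TRUE,TRUE
milkshake,Packaged milkshake,90,12,11,3,0.8,1.9,3.2,100,dairy;sugar_rich,TRUE,TRUE
plain_yogurt,Plain yogurt,61,4.7,4.7,3.3,0.8,2.1,3.5,121,dairy,FALSE,FALSE
fresh_cheese,Fresh cheese,98,3.5,3.5,4.5,1.1,2.8,11,185,dairy,FALSE,FALSE
orange_juice_fresh,Freshly squeezed orange juice,45,10.4,8.4,0.2,0.04,0.03,0.7,11,fruit_or_vegetable,TRUE,TRUE
packaged_juice,Packaged fruit juice drink,48,11.5,11,0.1,0.02,0.02,0.3,8,sugar_rich,TRUE,TRUE
soft_drink,Sugared soft drink,42,10.6,10.6,0,0,0,0,2,sugar_rich,TRUE,TRUE
water,Water,0,0,0,0,0,0,0,5,other,TRUE,FALSE
apple,Apple,52,13.8,10.4,0.2,0.01,0.03,0.3,6,fruit_or_vegetable,FALSE,FALSE
banana,Banana,89,22.8,12.2,0.3,0.03,0.11,1.1,5,fruit_or_vegetable,FALSE,FALSE
orange,Orange,47,11.8,9.4,0.1,0.02,0.02,0.9,40,fruit_or_vegetable,FALSE,FALSE
tomato,Tomato,18,3.9,2.6,0.2,0.03,0.03,0.9,10,fruit_or_vegetable,FALSE,FALSE
olive_oil,Virgin olive oil,884,0,0,100,73,14,0,1,olive_oil,FALSE,FALSE
butter,Butter,717,0.1,0.1,81,21,51,0.9,24,butter_margarine,FALSE,FALSE
margarine,Margarine,717,0.9,0.9,80,36,20,0.2,3,butter_margarine,FALSE,FALSE
serrano_ham,Serrano ham,241,0.5,0,16,7.2,5.5,23,12,other,FALSE,FALSE
boiled_egg,Boiled egg,155,1.1,1.1,11,4.1,3.3,13,50,other,FALSE,FALSE
cooked_rice,Cooked rice,130,28,0.1,0.3,0.1,0.1,2.7,10,other,FALSE,FALSE
cooked_pasta,Cooked pasta,158,31,0.6,0.9,0.1,0.2,5.8,7,other,FALSE,FALSE
chicken_breast,Grilled chicken breast,165,0,0,3.6,1.2,1,31,15,other,FALSE,FALSE
white_fish,Baked white fish,96,0,0,1.2,0.3,0.3,21,28,other,FALSE,FALSE
lentil_stew,Lentil stew,116,17,1.8,1.2,0.3,0.2,8,35,other,FALSE,FALSE
mixed_salad,Mixed salad,25,4,2.5,0.3,0.05,0.05,1.5,30,fruit_or_vegetable,FALSE,FALSE
fried_potato,Fried potato,312,41,0.3,15,9,2.2,3.4,12,other,FALSE,FALSE
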