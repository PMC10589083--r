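food_code,food_name,realm,subcategory,edible_portion,energy_kj_100g,protein_g_100g,calcium_mg_100g,iron_mg_100g,zinc_mg_100g,vita_ug_rae_100g,vitb12_100g,crustacean_type
catla,Catla (Catla catla),aquatic,carp,0.62,490,17.5,310,1.1,1.3,25,3.8,
rohu,Rohu (Labeo rohita),aquatic,carp,0.60,410,16.8,315,0.9,1.4,28,2.9,
mrigal,Mrigal (Cirrhinus cirrhosus),aquatic,carp,0.58,380,16.2,280,1.0,1.2,20,2.4,
silver_carp,Silver carp (Hypophthalmichthys molitrix),aquatic,carp,0.60,350,15.8,260,0.8,1.0,18,1.9,
tilapia,Nile tilapia (Oreochromis niloticus),aquatic,other_stocked_fish,0.55,400,18.0,45,0.7,0.9,12,1.6,
pangas,Striped catfish (Pangasianodon hypophthalmus),aquatic,other_stocked_fish,0.65,620,15.0,20,0.6,0.7,11,0.9,
koi,Climbing perch (Anabas testudineus),aquatic,other_stocked_fish,0.52,480,17.2,410,1.6,1.5,22,2.1,
silver_barb,Silver barb (Barbonymus gonionotus),aquatic,other_stocked_fish,0.55,420,16.5,240,1.2,1.3,16,1.7,
gulsha,Gulsha (Mystus cavasius),aquatic,other_stocked_fish,0.55,450,17.8,220,1.4,1.4,45,2.3,
mola,Mola (Amblypharyngodon mola),aquatic,unstocked_fish,0.85,430,17.3,850,5.7,3.2,1960,8.5,
tengra,Tengra (Mystus vittatus),aquatic,unstocked_fish,0.80,470,18.1,450,4.9,2.9,95,7.0,
pool_barb,Pool barb (Puntius sophore),aquatic,unstocked_fish,0.82,440,17.0,650,3.6,3.1,120,6.1,
taki,Spotted snakehead (Channa punctata),aquatic,unstocked_fish,0.60,390,16.9,180,2.2,1.8,55,3.2,
golda,Giant freshwater prawn (Macrobrachium rosenbergii),aquatic,crustaceans,0.45,370,18.9,210,1.8,1.6,15,1.2,prawn
bagda,Black tiger shrimp (Penaeus monodon),aquatic,crustaceans,0.50,360,19.5,145,1.5,1.4,12,1.1,shrimp
harina,Brown shrimp (Metapenaeus monoceros),aquatic,crustaceans,0.48,350,18.5,160,1.6,1.5,10,1.0,shrimp
rice,Paddy rice (husked equivalent),terrestrial,rice,0.95,1460,7.5,12,1.1,1.6,0,0,
red_amaranth,Red amaranth (lal shak),terrestrial,leafy_vegetables,0.78,180,3.5,230,5.0,0.9,720,0,
palong_shak,Spinach (palong shak),terrestrial,leafy_vegetables,0.72,120,2.8,110,3.2,0.7,480,0,
pumpkin,Sweet pumpkin,terrestrial,vitaminA_rich_vegetables,0.74,140,1.1,22,0.6,0.3,410,0,
carrot,Carrot,terrestrial,vitaminA_rich_vegetables,0.85,170,0.9,33,0.4,0.3,835,0,
okra,Okra,terrestrial,other_vegetables,0.86,140,1.9,82,0.7,0.6,19,0,
bottle_gourd,Bottle gourd,terrestrial,other_vegetables,0.77,60,0.6,24,0.3,0.2,8,0,
bitter_gourd,Bitter gourd,terrestrial,other_vegetables,0.84,80,1.0,19,0.8,0.5,24,0,
long_bean,Yard-long bean,terrestrial,other_vegetables,0.92,190,2.8,50,1.0,0.7,43,0,
eggplant,Eggplant (brinjal),terrestrial,other_vegetables,0.90,100,1.0,18,0.4,0.3,14,0,
potato,Potato,terrestrial,root_crops,0.82,320,2.0,10,0.8,0.4,1,0,
taro,Taro (mukhi kochu),terrestrial,root_crops,0.80,470,1.5,43,0.7,0.3,4,0,
mango,Ripe mango,terrestrial,vitaminA_rich_fruits,0.69,270,0.8,11,0.2,0.1,54,0,
papaya_ripe,Ripe papaya,terrestrial,vitaminA_rich_fruits,0.73,180,0.5,20,0.3,0.1,47,0,
banana,Banana,terrestrial,other_fruits,0.64,370,1.1,5,0.3,0.2,3,0,
guava,Guava,terrestrial,other_fruits,0.95,285,2.6,18,0.3,0.2,31,0,
coconut,Mature coconut,terrestrial,other_fruits,0.52,1480,3.3,14,2.4,1.1,0,0,
betel_nut,Betel nut (areca),terrestrial,nuts_oilseeds,0.70,1040,5.2,400,4.9,2.1,12,0,
mustard_seed,Mustard seed,terrestrial,nuts_oilseeds,1.00,2130,26.0,490,9.2,5.7,5,0,
sesame,Sesame seed,terrestrial,nuts_oilseeds,0.96,2390,18.0,975,14.6,7.8,3,0,
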