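"type","group","category"
"beer & wine","Alcoholic beverages","Sweets, snacks & alcohol"
"berries","Fruit","Vegetables & fruits"
"bread","Cereals & cereal-based products","Starches & grains"
"butter & cream","Fats & oils","Fats, oils & nuts"
"cheese","Dairy products (excl. milk)","Protein foods & dairy"
"chocolate & confectionery","Sweet dishes","Sweets, snacks & alcohol"
"coffee","NaNs beverages","Non-alcoholic beverages"
"condiments","Condiments & sauces","Prepared dishes & condiments"
"eggs","Eggs & meat substitutes","Protein foods & dairy"
"fish & seafood","Fish & seafood","Protein foods & dairy"
"fruit juice","Juice","Non-alcoholic beverages"
"fruiting vegetables","Vegetables","Vegetables & fruits"
"leafy vegetables","Vegetables","Vegetables & fruits"
"legumes","Potatoes, legumes & beans","Starches & grains"
"meat substitutes","Eggs & meat substitutes","Protein foods & dairy"
"milk","Milk & milk-based beverages","Protein foods & dairy"
"nuts & seeds","Seeds & nuts","Fats, oils & nuts"
"oils","Fats & oils","Fats, oils & nuts"
"pasta","Cereals & cereal-based products","Starches & grains"
"pastries & desserts","Sweet dishes","Sweets, snacks & alcohol"
"plant milk","Milk substitutes","Protein foods & dairy"
"pome & stone fruit","Fruit","Vegetables & fruits"
"poultry","Meat & poultry","Protein foods & dairy"
"processed meat","Unclassified meat","Protein foods & dairy"
"red meat","Meat & poultry","Protein foods & dairy"
"rice","Cereals & cereal-based products","Starches & grains"
"rice dishes","Rice, rice-based products","Starches & grains"
"root vegetables","Vegetables","Vegetables & fruits"
"salty snacks","Salty snacks","Sweets, snacks & alcohol"
"sauces","Condiments & sauces","Prepared dishes & condiments"
"soft drink","NaS beverages","Non-alcoholic beverages"
"soups","Soups","Prepared dishes & condiments"
"spirits & cocktails","Alcoholic beverages","Sweets, snacks & alcohol"
"sugar & honey","Sweeteners","Sweets, snacks & alcohol"
"tea","NaNs beverages","Non-alcoholic beverages"
"tubers","Potatoes, legumes & beans","Starches & grains"
"yogurt","Dairy products (excl. milk)","Protein foods & dairy"
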