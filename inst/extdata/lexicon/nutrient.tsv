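# Nutrient gazetteer: nutrients and chemical components.
# Stands in for the chemical-NER ensemble (any-vote union) used as the
# Nutrient dictionary; static list curated for offline reproducibility.
# Entries with an upper-case letter (Mg, ALA) match case-sensitively so the
# element symbol does not collide with the milligram unit symbol.
# No lemmatization for nutrients: the plural "omega-3s" is deliberately missed.
sodium	Nutrient
fiber	Nutrient
fibre	Nutrient
magnesium	Nutrient
Mg	Nutrient
potassium	Nutrient
protein	Nutrient
proteins	Nutrient
calcium	Nutrient
zinc	Nutrient
omega-3	Nutrient
vitamin	Nutrient
vitamins	Nutrient
mineral	Nutrient
minerals	Nutrient
iron	Nutrient
nickel	Nutrient
ALA	Nutrient
alpha-linolenic acid	Nutrient
carbohydrate	Nutrient
carbohydrates	Nutrient
cholesterol	Nutrient
sugar	Nutrient
sugars	Nutrient
folate	Nutrient
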