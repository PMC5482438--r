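# Quantity/Unit gazetteer: measurement-unit names and symbols in the style of
# the Units of Measurement Ontology, plus kitchen units (tablespoon, teaspoon).
# Matched on the lemma of each token; a slash-compound token (mg/day) matches
# through its pre-slash prefix. Bare time words (day, year) are omitted: the
# worked examples treat "per day" and "50 years" as non-unit tokens.
g	QuantityUnit
mg	QuantityUnit
kg	QuantityUnit
ug	QuantityUnit
µg	QuantityUnit
mcg	QuantityUnit
gram	QuantityUnit
kilogram	QuantityUnit
milligram	QuantityUnit
microgram	QuantityUnit
l	QuantityUnit
ml	QuantityUnit
dl	QuantityUnit
litre	QuantityUnit
liter	QuantityUnit
millilitre	QuantityUnit
milliliter	QuantityUnit
decilitre	QuantityUnit
deciliter	QuantityUnit
teaspoon	QuantityUnit
tablespoon	QuantityUnit
cup	QuantityUnit
ounce	QuantityUnit
oz	QuantityUnit
pound	QuantityUnit
lb	QuantityUnit
kcal	QuantityUnit
cal	QuantityUnit
calorie	QuantityUnit
kilocalorie	QuantityUnit
joule	QuantityUnit
kj	QuantityUnit
IU	QuantityUnit
mol	QuantityUnit
mmol	QuantityUnit
percent	QuantityUnit
%	QuantityUnit
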