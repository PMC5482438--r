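# Food gazetteer: general food and drink terms.
# Stands in for the semantic-tagger food/drink/plant/creature categories
# (F1-F4, L2, L3) used as the Food dictionary; static list curated for
# offline reproducibility. Lower-case entries match case-insensitively.
salt	Food
table salt	Food
milk	Food
cheese	Food
yogurt	Food
salmon	Food
tuna	Food
egg	Food
eggs	Food
bean	Food
beans	Food
vegetable	Food
vegetables	Food
nut	Food
nuts	Food
legume	Food
legumes	Food
flaxseed	Food
flaxseeds	Food
walnut	Food
walnuts	Food
fruit	Food
fruits	Food
pea	Food
peas	Food
soy	Food
soda	Food
food	Food
foods	Food
cereal	Food
cereals	Food
salad	Food
salads	Food
bread	Food
rice	Food
fish	Food
meat	Food
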