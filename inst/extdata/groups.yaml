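# Default target-group specifications (50 users each).
#
# diet_shares are generation quotas (enforced exactly by stratified
# assignment): percentages of omnivores, flexitarians, vegetarians and
# vegans. pct_innovative is a reference statistic that the group's attribute
# recipe is calibrated to reproduce emergently (innovation is always
# inferred from attributes, never imposed).
#
# age: either {kind: demographic} (national age curve) or
# {kind: range, min, max} (uniform). "Any age" groups are read as adult
# customers, uniform on 18-75; the senior group is uniform on 71-90.
# locality/region: either "national" (use the demographic reference shares)
# or explicit percentage maps; foodie and veggie communities are modelled as
# predominantly big-city dwellers.
groups:
  - name: Spanish
    n_users: 50
    pct_female: 52
    age: {kind: demographic}
    locality: national
    region: national
    diet_shares: {omnivore: 80, flexitarian: 16, vegetarian: 2, vegan: 2}
    pct_innovative: 45
  - name: Foodies
    n_users: 50
    pct_female: 44
    age: {kind: range, min: 18, max: 75}
    locality: {small: 0, medium: 10, large: 90}
    region: national
    diet_shares: {omnivore: 72, flexitarian: 20, vegetarian: 6, vegan: 2}
    pct_innovative: 88
  - name: Veggies
    n_users: 50
    pct_female: 70
    age: {kind: range, min: 18, max: 75}
    locality: {small: 0, medium: 10, large: 90}
    region: national
    diet_shares: {omnivore: 0, flexitarian: 50, vegetarian: 30, vegan: 20}
    pct_innovative: 88
  - name: Senior
    n_users: 50
    pct_female: 54
    age: {kind: range, min: 71, max: 90}
    locality: {small: 50, medium: 50, large: 0}
    region: national
    diet_shares: {omnivore: 98, flexitarian: 2, vegetarian: 0, vegan: 0}
    pct_innovative: 10
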