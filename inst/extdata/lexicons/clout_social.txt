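friend
friends
ally
allies
alliance
team
tribe
talk
talked
talking
tell
told
share
shared
help
helped
helping
trust
trusted
together
meet
meeting
join
joined
vote
voted
voting
plan
plans
partner
buddy
group
everyone
folks
people
family
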