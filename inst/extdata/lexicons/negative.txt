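sad
angry
mad
bad
hate
dislike
distrust
liar
weak
scared
stupid
mean
boring
awful
terrible
horrible
nasty
worst
lose
loser
danger
shaky
ashamed
bitter
enemy
hostile
useless
dishonest
anxious
cold
worried
fear
fearful
broken
annoyed
betray
sneaky
lazy
rotten
alone
false
harsh
unwelcome
threat
suspicious
paranoid
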