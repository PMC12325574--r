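happy
glad
great
good
love
like
trust
loyal
strong
brave
smart
kind
fun
amazing
awesome
wonderful
nice
best
win
winner
safe
solid
proud
sweet
friend
friendly
helpful
honest
calm
cool
excited
hope
hopeful
perfect
pleased
respect
reliable
super
thankful
together
true
warm
welcome
support
special
secure
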