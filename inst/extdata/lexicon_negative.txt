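sad
sadness
unhappy
miserable
depressed
depressing
gloomy
glum
down
downcast
blue
tearful
cried
crying
upset
distressed
troubled
worried
worry
anxious
anxiety
nervous
afraid
fear
fearful
scared
frightened
terrified
angry
anger
mad
furious
irritated
irritating
annoyed
annoying
frustrated
frustrating
tired
exhausted
weary
fatigued
drained
sluggish
weak
sick
ill
unwell
pain
painful
ache
aching
sore
hurt
hurting
lonely
loneliness
alone
isolated
abandoned
hopeless
helpless
useless
worthless
ashamed
embarrassed
guilty
regret
regretful
sorry
disappointed
disappointing
discouraged
dismal
dreadful
awful
terrible
horrible
bad
worse
worst
confused
confusing
forgetful
forgot
lost
overwhelmed
stressed
stressful
tense
uneasy
restless
bored
boring
dull
bleak
grim
heavy
bitter
resentful
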