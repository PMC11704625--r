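happy
happiness
joy
joyful
glad
cheerful
delighted
delightful
pleased
pleasant
wonderful
great
lovely
love
loved
enjoy
enjoyed
enjoyable
fun
excited
exciting
grateful
thankful
content
contented
satisfied
satisfying
proud
hopeful
optimistic
calm
peaceful
relaxed
relaxing
refreshed
energetic
energized
vibrant
alive
inspired
inspiring
amused
amusing
laughed
laughter
smile
smiled
smiling
warm
warmth
kind
kindness
friendly
welcoming
beautiful
gorgeous
splendid
marvelous
fantastic
terrific
excellent
superb
amazing
awesome
brilliant
bright
sunny
fresh
lucky
fortunate
blessed
comfort
comfortable
cozy
secure
confident
accomplished
productive
successful
rewarding
uplifting
encouraged
encouraging
cherished
treasured
appreciated
appreciative
serene
tranquil
blissful
elated
thrilled
overjoyed
gleeful
merry
jolly
radiant
sparkling
lively
spirited
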