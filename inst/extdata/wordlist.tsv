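word	pos
the	det
a	det
my	det
his	det
her	det
our	det
their	det
that	det
this	det
one	det
two	det
some	det
every	det
dog	noun
cat	noun
boy	noun
girl	noun
man	noun
bird	noun
fish	noun
tree	noun
house	noun
water	noun
apple	noun
mother	noun
father	noun
sister	noun
brother	noun
friend	noun
garden	noun
school	noun
table	noun
chair	noun
ball	noun
book	noun
door	noun
road	noun
horse	noun
cow	noun
farm	noun
barn	noun
cake	noun
milk	noun
rain	noun
snow	noun
sun	noun
hat	noun
coat	noun
shoe	noun
bed	noun
room	noun
yard	noun
park	noun
store	noun
game	noun
song	noun
story	noun
lunch	noun
dinner	noun
morning	noun
night	noun
day	noun
week	noun
summer	noun
winter	noun
window	noun
basket	noun
letter	noun
flower	noun
rabbit	noun
wagon	noun
box	noun
cup	noun
ran	verb
sat	verb
saw	verb
found	verb
made	verb
took	verb
gave	verb
put	verb
got	verb
had	verb
went	verb
came	verb
played	verb
walked	verb
jumped	verb
looked	verb
helped	verb
liked	verb
wanted	verb
asked	verb
called	verb
opened	verb
closed	verb
washed	verb
cleaned	verb
painted	verb
carried	verb
dropped	verb
filled	verb
moved	verb
showed	verb
told	verb
read	verb
ate	verb
held	verb
kept	verb
left	verb
heard	verb
big	adj
small	adj
old	adj
new	adj
red	adj
blue	adj
green	adj
little	adj
happy	adj
warm	adj
cold	adj
wet	adj
dry	adj
tall	adj
short	adj
kind	adj
nice	adj
soft	adj
dark	adj
bright	adj
clean	adj
round	adj
young	adj
quiet	adj
slow	adj
in	prep
on	prep
at	prep
by	prep
near	prep
with	prep
under	prep
over	prep
into	prep
from	prep
and	conj
but	conj
so	conj
fast	adv
well	adv
soon	adv
today	adv
again	adv
away	adv
home	adv
there	adv
slowly	adv
quietly	adv
outside	adv
inside	adv
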