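# bundled deterministic tagger lookup: surface -> (lemma, upos)
surface	lemma	upos
a	a	OTHER
an	a	OTHER
the	the	OTHER
this	this	OTHER
that	that	OTHER
these	these	OTHER
those	those	OTHER
which	which	OTHER
who	who	OTHER
what	what	OTHER
i	i	OTHER
me	i	OTHER
my	my	OTHER
you	you	OTHER
your	your	OTHER
he	he	OTHER
she	she	OTHER
it	it	OTHER
we	we	OTHER
they	they	OTHER
them	they	OTHER
us	we	OTHER
is	be	VERB
am	be	VERB
are	be	VERB
was	be	VERB
were	be	VERB
be	be	VERB
been	be	VERB
being	be	VERB
has	have	VERB
have	have	VERB
had	have	VERB
do	do	VERB
does	do	VERB
did	do	VERB
dont	do	VERB
goes	go	VERB
go	go	VERB
went	go	VERB
gone	go	VERB
ran	run	VERB
run	run	VERB
runs	run	VERB
running	run	VERB
ask	ask	VERB
asks	ask	VERB
asked	ask	VERB
asking	ask	VERB
inquire	inquire	VERB
inquired	inquire	VERB
inquires	inquire	VERB
say	say	VERB
said	say	VERB
says	say	VERB
think	think	VERB
thought	think	VERB
know	know	VERB
knew	know	VERB
feel	feel	VERB
felt	feel	VERB
and	and	OTHER
or	or	OTHER
but	but	OTHER
not	not	OTHER
no	no	OTHER
yes	yes	OTHER
to	to	OTHER
of	of	OTHER
in	in	OTHER
on	on	OTHER
at	at	OTHER
for	for	OTHER
with	with	OTHER
so	so	OTHER
if	if	OTHER
then	then	OTHER
um	um	OTHER
uh	uh	OTHER
like	like	OTHER
dog	dog	NOUN
dogs	dog	NOUN
cat	cat	NOUN
cats	cat	NOUN
week	week	NOUN
weeks	week	NOUN
day	day	NOUN
days	day	NOUN
time	time	NOUN
times	time	NOUN
thing	thing	NOUN
things	thing	NOUN
people	person	NOUN
person	person	NOUN
work	work	NOUN
school	school	NOUN
karaoke	karaoke	NOUN
friend	friend	NOUN
friends	friend	NOUN
family	family	NOUN
big	big	ADJ
small	small	ADJ
good	good	ADJ
better	good	ADJ
best	good	ADJ
bad	bad	ADJ
fine	fine	ADJ
busy	busy	ADJ
talkative	talkative	ADJ
happy	happy	ADJ
formal	formal	ADJ
new	new	ADJ
old	old	ADJ
quickly	quickly	ADV
slowly	slowly	ADV
really	really	ADV
very	very	ADV
lately	lately	ADV
well	well	ADV
here	here	ADV
there	there	ADV
now	now	ADV
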