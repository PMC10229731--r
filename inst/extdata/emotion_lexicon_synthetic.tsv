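term	variants	category
angry	anger,angrily,angered	anger
furious	fury,furiously	anger
annoyed	annoy,annoyance,annoying	anger
irritated	irritation,irritating,irritable	anger
mad	maddened,maddening	anger
enraged	rage,raging	anger
outraged	outrage,outrageous	anger
resentful	resentment,resent,resented	anger
frustrated	frustration,frustrating	anger
livid		anger
cross		anger
aggravated	aggravation,aggravating	anger
indignant	indignation	anger
infuriated	infuriating	anger
irate		anger
fuming	fumed	anger
bitter	bitterness,bitterly	anger
hostile	hostility	anger
vengeful	vengeance	anger
hateful	hate,hated,hates,hating,hatred	anger
exasperated	exasperation,exasperating	anger
offended	offense	anger
seething	seethe	anger
wrathful	wrath	anger
afraid		anxiety
scared	scare,scares,scary	anxiety
frightened	frighten,frightening,fright	anxiety
terrified	terrify,terrifying,terror	anxiety
anxious	anxiety,anxiously	anxiety
nervous	nervously,nervousness	anxiety
worried	worry,worries,worrying	anxiety
fearful	fear,fears,feared,fearfully	anxiety
panicked	panic,panicky,panicking	anxiety
apprehensive	apprehension	anxiety
uneasy	unease,uneasiness	anxiety
alarmed	alarm,alarming	anxiety
dread	dreading,dreaded,dreadful	anxiety
petrified		anxiety
tense	tension	anxiety
stressed	stress,stressful	anxiety
threatened		anxiety
jittery	jitters	anxiety
horrified	horror,horrifying,horrid	anxiety
shaken		anxiety
startled		anxiety
paranoid	paranoia	anxiety
insecure	insecurity	anxiety
overwhelmed		anxiety
spooked		anxiety
timid	timidity	anxiety
sad	sadness,sadly,saddened	sadness
unhappy	unhappiness,unhappily	sadness
depressed	depression,depressing	sadness
miserable	misery,miserably	sadness
heartbroken	heartbreak,heartbreaking	sadness
gloomy	gloom	sadness
downhearted		sadness
sorrowful	sorrow,sorrows	sadness
grieving	grief,grieved,grieve	sadness
mournful	mourn,mourning	sadness
devastated	devastating,devastation	sadness
despairing	despair,despaired	sadness
hopeless	hopelessness,hopelessly	sadness
lonely	loneliness,lonesome	sadness
dejected	dejection	sadness
despondent	despondency	sadness
disheartened		sadness
distraught		sadness
tearful	tearfully	sadness
crushed		sadness
melancholy	melancholic	sadness
homesick	homesickness	sadness
disappointed	disappointment,disappointing	sadness
forlorn		sadness
anguished	anguish	sadness
woeful	woe	sadness
heavyhearted		sadness
happy	happiness,happily	positive
glad	gladly,gladness	positive
joyful	joy,joyous,joyfully	positive
delighted	delight,delightful	positive
pleased	pleasure,pleasing	positive
cheerful	cheery,cheerfulness	positive
excited	excitement,exciting,excitedly	positive
thrilled	thrill,thrilling	positive
contented	contentment	positive
proud	pride,proudly	positive
grateful	gratitude,gratefully	positive
thankful	thankfulness	positive
elated	elation	positive
ecstatic	ecstasy	positive
hopeful	hopefulness,hopefully	positive
relieved	relief	positive
amused	amusement,amusing	positive
loving	love,loved,loves,lovingly	positive
adoring	adore,adored,adoration	positive
affectionate	affection	positive
satisfied	satisfaction,satisfying	positive
enthusiastic	enthusiasm	positive
optimistic	optimism	positive
flattered	flattering	positive
euphoric	euphoria	positive
overjoyed		positive
confident	confidence,confidently	positive
serene	serenity	positive
amazed	amazement	positive
blissful	bliss	positive
jubilant	jubilation	positive
upset	upsetting	negative
guilty	guilt,guiltily	negative
ashamed	shame,shameful	negative
embarrassed	embarrassment,embarrassing	negative
humiliated	humiliation,humiliating	negative
jealous	jealousy,jealously	negative
envious	envy	negative
bored	boredom,boring	negative
disgusted	disgust,disgusting	negative
helpless	helplessness	negative
powerless	powerlessness	negative
vulnerable	vulnerability	negative
distressed	distress,distressing	negative
troubled		negative
disturbed	disturbing	negative
betrayed	betrayal	negative
remorseful	remorse	negative
regretful	regret,regrets,regretted	negative
repulsed	repulsion	negative
uncomfortable	discomfort	negative
surprised	surprise,surprising	other_affect
shocked	shock,shocking	other_affect
stunned		other_affect
numb	numbness	other_affect
moved		other_affect
touched		other_affect
sympathetic	sympathy	other_affect
compassionate	compassion	other_affect
pity	pitying	other_affect
nostalgic	nostalgia	other_affect
awestruck	awe	other_affect
longing	yearning	other_affect
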