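category,term
suicide_seeking,commit suicide
suicide_seeking,how to commit suicide
suicide_seeking,how to kill myself
suicide_seeking,kill myself
suicide_seeking,want to die
suicide_seeking,ways to kill yourself
suicide_seeking,painless suicide
suicide_seeking,painless death
suicide_seeking,end my life
suicide_seeking,take my own life
suicide_seeking,suicide methods
suicide_seeking,how to hang yourself
suicide_seeking,overdose to die
suicide_seeking,lethal dose
suicide_seeking,jump off bridge
suicide_seeking,how to tie a noose
suicide_seeking,quick death
suicide_seeking,easiest way to die
suicide_seeking,pills to die
suicide_seeking,carbon monoxide suicide
suicide_prevention,suicide hotline
suicide_prevention,suicide prevention
suicide_prevention,crisis line
suicide_prevention,crisis hotline
suicide_prevention,suicide help
suicide_prevention,suicidal thoughts help
suicide_prevention,suicide counseling
suicide_prevention,stop suicidal thoughts
suicide_prevention,help a suicidal friend
suicide_prevention,suicide warning signs
suicide_prevention,suicide support group
suicide_prevention,lifeline phone number
suicide_prevention,talk to a counselor
suicide_prevention,crisis text line
suicide_prevention,mental health emergency
suicide_neutral,suicides
suicide_neutral,suicide
suicide_neutral,suicide rate
suicide_neutral,suicide statistics
suicide_neutral,suicide definition
suicide_neutral,suicide news
suicide_neutral,celebrity suicide
suicide_neutral,suicide note
suicide_neutral,suicide attempt
suicide_neutral,suicidal ideation
suicide_neutral,self harm
suicide_neutral,self injury
suicide_neutral,suicide documentary
suicide_neutral,suicide survivor
mood_anxiety,depressed
mood_anxiety,depression
mood_anxiety,am i depressed
mood_anxiety,depression test
mood_anxiety,depression symptoms
mood_anxiety,major depression
mood_anxiety,clinical depression
mood_anxiety,anxiety
mood_anxiety,anxiety attack
mood_anxiety,panic attack
mood_anxiety,anxiety symptoms
mood_anxiety,social anxiety
mood_anxiety,generalized anxiety disorder
mood_anxiety,bipolar
mood_anxiety,bipolar disorder
mood_anxiety,mood swings
mood_anxiety,feeling hopeless
mood_anxiety,feeling worthless
mood_anxiety,crying for no reason
mood_anxiety,cant sleep depressed
mood_anxiety,antidepressants
mood_anxiety,sertraline
mood_anxiety,fluoxetine
mood_anxiety,therapy for depression
mood_anxiety,sad all the time
psychosis,delusion
psychosis,delusions
psychosis,hallucination
psychosis,hallucinations
psychosis,hearing voices
psychosis,schizophrenia
psychosis,schizophrenia symptoms
psychosis,psychosis
psychosis,psychotic episode
psychosis,paranoia
psychosis,paranoid
psychosis,voices in my head
psychosis,seeing things
psychosis,antipsychotic
psychosis,risperidone
psychosis,schizoaffective
psychosis,losing my mind
stressor_trauma,social isolation
stressor_trauma,lonely
stressor_trauma,loneliness
stressor_trauma,i have no friends
stressor_trauma,divorce
stressor_trauma,breakup
stressor_trauma,lost my job
stressor_trauma,unemployed
stressor_trauma,debt stress
stressor_trauma,foreclosure
stressor_trauma,eviction
stressor_trauma,grief
stressor_trauma,death of a loved one
stressor_trauma,ptsd
stressor_trauma,trauma
stressor_trauma,abuse
stressor_trauma,domestic violence
stressor_trauma,bullying
stressor_trauma,chronic pain
stressor_trauma,stress
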