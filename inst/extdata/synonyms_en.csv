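word,synonym
community,neighborhood
resilience,robustness
emergency,crisis
hospital,clinic
disease,illness
epidemic,outbreak
response,reaction
support,assistance
infrastructure,facilities
network,web
capacity,capability
assessment,evaluation
indicator,measure
health,wellbeing
safety,security
plan,strategy
resource,asset
risk,hazard
urban,city
rural,countryside
public,civic
medical,clinical
social,communal
mental,psychological
green,verdant
space,area
system,framework
data,information
local,regional
global,worldwide
rapid,fast
strong,sturdy
weak,fragile
large,big
small,little
improve,enhance
reduce,lessen
increase,raise
build,construct
monitor,track
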