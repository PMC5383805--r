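# Frozen public-suffix rule snapshot (one suffix per line).
# Registrable domain = one label + the longest matching suffix below;
# hosts matching no rule fall back to their last two labels.
com
net
org
edu
gov
mil
int
info
biz
name
pro
aero
coop
museum
tv
io
co
me
us
state.us
k12.us
uk
co.uk
org.uk
net.uk
ac.uk
gov.uk
me.uk
fr
de
it
nl
es
ca
gc.ca
au
com.au
net.au
org.au
edu.au
gov.au
jp
co.jp
ne.jp
or.jp
ac.jp
go.jp
cn
com.cn
org.cn
ru
ch
at
be
se
no
dk
fi
pl
br
com.br
net.br
org.br
gov.br
mx
com.mx
in
co.in
net.in
org.in
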