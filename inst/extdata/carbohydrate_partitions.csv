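structure,s,t,count
arabinose,1,3,4
arabinose,2,2,1
arabinose,2,3,2
arabinose,3,3,3
galactose,1,2,1
galactose,1,3,4
galactose,2,3,3
galactose,3,3,4
maltose,1,2,2
maltose,1,3,6
maltose,2,3,8
maltose,3,3,8
sucrose,1,2,3
sucrose,1,3,5
sucrose,2,3,9
sucrose,3,3,7
sorbose,1,2,1
sorbose,1,3,3
sorbose,1,4,1
sorbose,2,2,1
sorbose,2,3,1
sorbose,2,4,2
sorbose,3,3,2
sorbose,3,4,1
ribose,1,2,1
ribose,1,3,3
ribose,2,3,3
ribose,3,3,3
hmf,1,2,3
hmf,1,3,1
hmf,2,3,6
raffinose,1,2,3
raffinose,1,3,8
raffinose,2,2,1
raffinose,2,3,9
raffinose,2,4,3
raffinose,3,3,9
raffinose,3,4,1
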