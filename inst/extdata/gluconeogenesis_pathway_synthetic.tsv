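# Synthetic fixture: 10-step gluconeogenesis (2 pyruvate -> glucose 6-phosphate)
# written in the gluconeogenic direction. dg0_prime_kj_mol are
# literature-style placeholder estimates of standard transformed Gibbs
# energies (pH 7, I = 250 mM, 298.15 K), NOT component-contribution ground
# truth; analyses built on this file test orderings and solver behavior,
# never these absolute values. flux is the relative pathway flux used for
# cumulative profiles (2 for the steps before the triose condensation).
reaction_id	formula	dg0_prime_kj_mol	flux
pyc	pyruvate + atp + hco3 = oaa + adp + pi	-0.5	2
pck	oaa + atp = pep + adp + co2	1.0	2
eno	pep + h2o = 2pg	4.0	2
pgm	2pg = 3pg	-4.4	2
pgk	3pg + atp = bpg + adp	18.5	2
gapdh	bpg + nadh = g3p + nad + pi	-7.5	2
tpi	g3p = dhap	-5.5	1
fba	g3p + dhap = fbp	-19.8	1
fbpase	fbp + h2o = f6p + pi	-11.5	1
pgi	f6p = g6p	-2.5	1
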