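#ifndef SPANBVS_POLYAGAMMA_H
#define SPANBVS_POLYAGAMMA_H

// One draw from the Polya-Gamma distribution PG(b, c), b > 0 real.
// Uses R's RNG; caller must hold an RNG scope.
double rpg_one(double b, double c);

#endif
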