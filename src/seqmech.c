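/* Right-hand side of the reduced mass-action system for a sequential
 * enzyme-substrate mechanism:
 *
 *   E + S <=> C1 <=> C2 <=> ... <=> Cn  [-> EP  [<=> E + P]]
 *
 * The state vector carries only the complexes (C1..Cn, EP, P); free enzyme
 * and free substrate are reconstructed from the conservation totals e0 and
 * s0, so both mass balances hold to rounding error by construction.
 *
 * Parameter vector (padded to SEQ_NPAR doubles on the R side):
 *   p[0] n_rev   p[1] include_catalysis   p[2] include_release
 *   p[3] e0      p[4] s0
 *   p[5 .. 4+n]        k_fwd[1..n]   (step 1 in 1/M/s, others 1/s)
 *   p[5+n .. 4+2n]     k_rev[1..n]   (1/s)
 *   p[5+2n] k_r        p[6+2n] k_on (E+P association, 1/M/s)
 *   p[7+2n] k_off      (EP dissociation, 1/s)
 */
#include <R.h>

#define SEQ_NPAR 64
#define SEQ_MAX_REV 28

static double p[SEQ_NPAR];

void seq_init(void (*odeparms)(int *, double *))
{
    int n = SEQ_NPAR;
    odeparms(&n, p);
}

void seq_rhs(int *neq, double *t, double *y, double *ydot,
             double *yout, int *ip)
{
    int n = (int) p[0], cat = (int) p[1], rel = (int) p[2];
    double e0 = p[3], s0 = p[4];
    const double *kf = p + 5, *kr = p + 5 + n;
    double k_r = p[5 + 2 * n], k_on = p[6 + 2 * n], k_off = p[7 + 2 * n];
    double v[SEQ_MAX_REV];
    double sumC = 0.0;
    int i;

    for (i = 0; i < n; i++) sumC += y[i];
    double EP = cat ? y[n] : 0.0;
    double P  = rel ? y[n + 1] : 0.0;
    double E = e0 - sumC - EP;
    double S = s0 - sumC - EP - P;

    v[0] = kf[0] * E * S - kr[0] * y[0];
    for (i = 1; i < n; i++) v[i] = kf[i] * y[i - 1] - kr[i] * y[i];
    double vcat = cat ? k_r * y[n - 1] : 0.0;
    double vrel = rel ? (k_off * EP - k_on * E * P) : 0.0;

    for (i = 0; i < n; i++)
        ydot[i] = v[i] - ((i < n - 1) ? v[i + 1] : vcat);
    if (cat) ydot[n] = vcat - vrel;
    if (rel) ydot[n + 1] = vrel;
}
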