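/* Generic mass-action reaction-network RHS for deSolve.
 *
 * The network is packed into a fixed-length double vector (see
 * pack_network() on the R side):
 *   p[0]          number of states  (ns)
 *   p[1]          number of reactions (nr)
 *   p[2]          stimulus concentration u (constant input)
 *   p[3 .. 3+nr)                rate constants k_j
 *   p[3+nr .. 3+2nr)            stimulus order per reaction (0 or 1)
 *   p[3+2nr .. 3+6nr)           4 per reaction: i1, o1, i2, o2
 *                               (1-based reactant state index, kinetic order;
 *                                index 0 = unused slot)
 *   p[3+6nr]                    number of stoichiometry triplets (nt)
 *   p[4+6nr .. 4+6nr+3nt)       3 per triplet: state (1-based),
 *                               reaction (1-based), net coefficient
 *
 * Flux j = k_j * u^{stim_j} * x[i1]^{o1} * x[i2]^{o2};
 * dx = sum over triplets of coeff * flux.
 */

#include <math.h>

#define KIN_PACKLEN 4096
#define KIN_MAXRXN  256

static double kin_p[KIN_PACKLEN];

void kin_init(void (*odeparms)(int *, double *))
{
    int n = KIN_PACKLEN;
    odeparms(&n, kin_p);
}

void kin_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const int ns = (int) kin_p[0];
    const int nr = (int) kin_p[1];
    const double u = kin_p[2];
    const double *k    = kin_p + 3;
    const double *sord = kin_p + 3 + nr;
    const double *rx   = kin_p + 3 + 2 * nr;
    const int nt = (int) kin_p[3 + 6 * nr];
    const double *tr = kin_p + 4 + 6 * nr;
    double v[KIN_MAXRXN];
    int i, j;

    for (i = 0; i < ns; i++) ydot[i] = 0.0;

    for (j = 0; j < nr; j++) {
        double f = k[j];
        if (sord[j] > 0.0)
            f *= (sord[j] == 1.0) ? u : pow(u, sord[j]);
        {
            int i1 = (int) rx[4 * j];
            if (i1 > 0) {
                double o = rx[4 * j + 1];
                double x = y[i1 - 1];
                f *= (o == 1.0) ? x : ((o == 2.0) ? x * x : pow(x, o));
            }
        }
        {
            int i2 = (int) rx[4 * j + 2];
            if (i2 > 0) {
                double o = rx[4 * j + 3];
                double x = y[i2 - 1];
                f *= (o == 1.0) ? x : ((o == 2.0) ? x * x : pow(x, o));
            }
        }
        v[j] = f;
    }

    for (i = 0; i < nt; i++) {
        int si = (int) tr[3 * i] - 1;
        int rj = (int) tr[3 * i + 1] - 1;
        ydot[si] += tr[3 * i + 2] * v[rj];
    }
}
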