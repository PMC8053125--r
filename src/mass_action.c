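/* Generic mass-action right-hand side for deSolve's compiled-code interface.
 *
 * The reaction network is passed through `parms` as a flat vector padded to
 * APTKIN_PMAX doubles (deSolve's odeparms copies a fixed length):
 *   parms[0] = n_species
 *   parms[1] = n_steps (elementary irreversible steps)
 *   then 7 slots per step:
 *     n_reactants, reactant1, reactant2, n_products, product1, product2, k
 * Species indices are 0-based; unused slots are -1.
 */
#include <R.h>

#define APTKIN_PMAX 256

static double aptkin_parms[APTKIN_PMAX];

void ma_init(void (*odeparms)(int *, double *))
{
    int n = APTKIN_PMAX;
    odeparms(&n, aptkin_parms);
}

void ma_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const double *p = aptkin_parms;
    int ns = (int) p[0];
    int nsteps = (int) p[1];
    int i, s;
    const double *q;

    for (i = 0; i < ns; i++) ydot[i] = 0.0;

    q = p + 2;
    for (s = 0; s < nsteps; s++, q += 7) {
        int n_react = (int) q[0];
        int r1 = (int) q[1];
        int r2 = (int) q[2];
        int n_prod = (int) q[3];
        int p1 = (int) q[4];
        int p2 = (int) q[5];
        double v = q[6] * y[r1];
        if (n_react == 2) v *= y[r2];
        ydot[r1] -= v;
        if (n_react == 2) ydot[r2] -= v;
        ydot[p1] += v;
        if (n_prod == 2) ydot[p2] += v;
    }
}
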