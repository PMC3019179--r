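/* Table-driven right-hand side for the AT1R gene regulatory network.
 *
 * The network (flux kinds, participant indices, stoichiometry with
 * compartment-volume scaling, and parameter values) is encoded on the R
 * side into a flat double vector; see .encode_network() in R/compiled.R.
 *
 * Layout of the parms vector (0-based):
 *   [0] n_par     number of kinetic parameter values
 *   [1] n_state   number of ODE states
 *   [2] n_flux    number of elementary fluxes
 *   [3] n_stoich  number of (flux, state, coef) triplets
 *   [4] off_flux  offset of the flux table
 *   [5] off_sto   offset of the stoichiometry triplets
 *   [6] off_par   offset of the parameter values
 *   [7] reserved
 * Flux records are 6 doubles: kind, i1, i2, ifor, ip1, ip2 where
 *   kind 1: MM driven by forcing ifor scaled by parameter i2:
 *           v = p[ip1] * p[i2] * F[ifor] * S1 / (p[ip2] + S1)
 *   kind 2: MM, constant enzyme folded into Vmax:
 *           v = p[ip1] * S1 / (p[ip2] + S1)
 *   kind 3: first order / unimolecular mass action: v = p[ip1] * S1
 *   kind 4: bimolecular mass action: v = p[ip1] * S1 * S2
 *   kind 5: homodimerization: v = p[ip1] * S1 * S1
 * Negative state excursions of solver-tolerance size are treated as zero
 * concentration when evaluating fluxes.
 */

#include <R.h>

#define AP1_MAXPAR 4096
#define AP1_NFORC 3

static double ap1_parms[AP1_MAXPAR];
static double ap1_forc[AP1_NFORC];

void ap1grn_initpar(void (*odeparms)(int *, double *))
{
    int n = AP1_MAXPAR;
    odeparms(&n, ap1_parms);
}

void ap1grn_initforc(void (*odeforcs)(int *, double *))
{
    int n = AP1_NFORC;
    odeforcs(&n, ap1_forc);
}

void ap1grn_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double *h = ap1_parms;
    int n_flux = (int) h[2];
    int n_sto  = (int) h[3];
    int off_flux = (int) h[4];
    int off_sto  = (int) h[5];
    const double *p = h + (int) h[6];
    double flux[256];
    int f, i;

    for (f = 0; f < n_flux; f++) {
        const double *rec = h + off_flux + 6 * f;
        int kind = (int) rec[0];
        int i1 = (int) rec[1];
        int i2 = (int) rec[2];
        int ifor = (int) rec[3];
        int ip1 = (int) rec[4];
        int ip2 = (int) rec[5];
        double s1 = (i1 >= 0 && y[i1] > 0.0) ? y[i1] : 0.0;
        double v = 0.0;

        switch (kind) {
        case 1: {
            double e = p[i2] * ap1_forc[ifor];
            v = p[ip1] * e * s1 / (p[ip2] + s1);
            break;
        }
        case 2:
            v = p[ip1] * s1 / (p[ip2] + s1);
            break;
        case 3:
            v = p[ip1] * s1;
            break;
        case 4: {
            double s2 = (i2 >= 0 && y[i2] > 0.0) ? y[i2] : 0.0;
            v = p[ip1] * s1 * s2;
            break;
        }
        case 5:
            v = p[ip1] * s1 * s1;
            break;
        }
        flux[f] = v;
    }

    for (i = 0; i < *neq; i++) ydot[i] = 0.0;
    for (i = 0; i < n_sto; i++) {
        const double *tr = h + off_sto + 3 * i;
        ydot[(int) tr[1]] += tr[2] * flux[(int) tr[0]];
    }
}
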