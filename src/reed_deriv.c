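#include <R.h>
#include <math.h>

/* Right-hand side of the coupled reed-bank equations of motion, in the
 * first-order form used by deSolve:
 *
 *   x_j' = v_j
 *   v_j' = -gamma*w_j*v_j - w_j^2*x_j + F_j*sin(omega*t)
 *          + k_{j-1,j}*(x_{j-1}-x_j) + k_{j,j+1}*(x_{j+1}-x_j)
 *
 * Missing links at the chain ends contribute nothing (free ends).
 *
 * Parameter block layout (padded to REED_PARMS_MAX on the R side because
 * deSolve requires the parms vector length to match this static array):
 *   [0]               n (number of reeds)
 *   [1]               omega, drive angular frequency in rad/s (0 => unforced)
 *   [2        .. 2+n-1]   w_j^2
 *   [2+n      .. 2+2n-1]  gamma*w_j
 *   [2+2n     .. 2+3n-1]  F_j = f0 * mask_j
 *   [2+3n     .. 2+4n-2]  per-link coupling (n-1 values)
 */
#define REED_PARMS_MAX 4224

static double parms[REED_PARMS_MAX];

void reed_init(void (*odeparms)(int *, double *))
{
    int N = REED_PARMS_MAX;
    odeparms(&N, parms);
}

void reed_deriv(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    int n = (int) parms[0];
    double omega = parms[1];
    const double *wj2  = parms + 2;
    const double *gw   = parms + 2 + n;
    const double *famp = parms + 2 + 2 * n;
    const double *kl   = parms + 2 + 3 * n;
    const double *x = y, *v = y + n;
    double *dx = ydot, *dv = ydot + n;
    double s = (omega > 0.0) ? sin(omega * (*t)) : 0.0;
    int j;

    for (j = 0; j < n; j++) {
        double c = 0.0;
        if (j > 0)
            c += kl[j - 1] * (x[j - 1] - x[j]);
        if (j < n - 1)
            c += kl[j] * (x[j + 1] - x[j]);
        dx[j] = v[j];
        dv[j] = -gw[j] * v[j] - wj2[j] * x[j] + famp[j] * s + c;
    }
}
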