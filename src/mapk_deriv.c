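/* Four-state rescaled MAPK cascade with switchable feedback.
 *
 * States: x1 = pRaf, x2 = ppMEK, x3 = pERK, x4 = ppERK, all fractions of
 * total protein (totals rescaled to 1; silencing enters via s1..s3).
 *
 * Parameter block passed from R (length 21, order fixed):
 *   [0..11]  k1p k2p k3p k4p k1m k2m k3m k4m kFn kFp g K
 *   [12..20] fp fn s1 s2 s3 ku mek_inhibited feedback_removed t_off
 */
#include <R.h>
#include <math.h>

#define N_PARMS 21

static double parms[N_PARMS];

void initmod_mapk(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double input_u(double t)
{
    double ku = parms[17], K = parms[11], t_off = parms[20];
    double t3;
    if (t < 0.0 || t >= t_off)
        return 0.0;
    t3 = t * t * t;
    return ku * (1.0 - t3 / (t3 + K * K * K));
}

void derivs_mapk(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double k1p = parms[0], k2p = parms[1], k3p = parms[2], k4p = parms[3];
    double k1m = parms[4], k2m = parms[5], k3m = parms[6], k4m = parms[7];
    double kFn = parms[8], kFp = parms[9], g = parms[10];
    double fp = parms[12], fn = parms[13];
    double s1 = parms[14], s2 = parms[15], s3 = parms[16];
    double x1 = y[0], x2 = y[1], x3 = y[2], x4 = y[3];
    double u, h, yg, act1, deact1;

    if (parms[18] != 0.0)       /* MEK inhibited */
        k2p = 0.0;
    if (parms[19] != 0.0) {     /* feedback removed */
        kFp = 0.0;
        kFn = 0.0;
    }

    u = input_u(*t);
    if (x4 > 0.0) {
        yg = pow(x4, g);
        h = yg / (1.0 + yg);
    } else {
        h = 0.0;
    }

    act1 = k1p * u + fp * kFp * h;
    deact1 = k1m + fn * kFn * x4;

    ydot[0] = act1 * (s1 - x1) - deact1 * x1;
    ydot[1] = k2p * x1 * (s2 - x2) - k2m * x2;
    ydot[2] = k3p * x2 * (s3 - x3 - x4) - k3m * x3
              - k4p * x2 * x3 + k4m * x4;
    ydot[3] = k4p * x2 * x3 - k4m * x4;
}
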