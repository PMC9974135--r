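/* Compiled right-hand side of the exercise-extended glucose-insulin model,
 * in the deSolve compiled-model convention. State order:
 *   0 Q1, 1 Q2, 2 X, 3 I, 4 x1, 5 x2,
 *   6 Y, 7 tPA, 8 PAint, 9 th, 10 Z, 11 rGU, 12 rGP, 13 rdepl
 * Forcings: forc[0] = AC(t) [counts/min], forc[1] = ub(t) [uU/min].
 * Meal appearance Ra(t) is computed analytically from per-meal parameters
 * appended to the parameter vector. */

#include <R.h>
#include <math.h>

#define N_FIXED 38
#define MAX_MEALS 24
#define N_PARMS (N_FIXED + 3 * MAX_MEALS)

static double parms[N_PARMS];
static double forc[2];

#define p1     parms[0]
#define p2     parms[1]
#define p3     parms[2]
#define p4     parms[3]
#define p5     parms[4]
#define Vg     parms[5]
#define BW     parms[6]
/* parms[7] = Gb (not used directly in the RHS) */
#define tauAC  parms[8]
#define tauZ   parms[9]
#define bgain  parms[10]
#define aY     parms[11]
#define n1     parms[12]
#define aAC    parms[13]
#define n2     parms[14]
#define ah     parms[15]
#define tp     parms[16]
#define q5     parms[17]
#define q1     parms[18]
#define q2     parms[19]
#define q3l    parms[20]
#define q4l    parms[21]
#define q3h    parms[22]
#define q4h    parms[23]
#define q6     parms[24]
#define adepl  parms[25]
#define bdepl  parms[26]
#define beta   parms[27]
#define rGPb   parms[28]
#define alpha  parms[29]
#define k1     parms[30]
#define k2     parms[31]
#define k3     parms[32]
#define k4     parms[33]
#define VI     parms[34]
#define Xb     parms[35]
#define Q1b    parms[36]
#define nmeals parms[37]

void initglucopa(void (*odeparms)(int *, double *))
{
    int N = N_PARMS;
    odeparms(&N, parms);
}

void forcglucopa(void (*odeforcs)(int *, double *))
{
    int N = 2;
    odeforcs(&N, forc);
}

/* overflow-safe Hill switch (x/p)^n / (1 + (x/p)^n) evaluated in log space */
static double hill(double x, double p, double n)
{
    double e;
    if (x <= 0.0) return 0.0;
    e = -n * (log(x) - log(p));
    if (e > 700.0) return 0.0;
    return 1.0 / (1.0 + exp(e));
}

static double meal_ra_total(double t)
{
    int i, nm = (int)(nmeals + 0.5);
    double ra = 0.0;
    for (i = 0; i < nm; i++) {
        double t0 = parms[N_FIXED + 3 * i];
        double fD = parms[N_FIXED + 3 * i + 1]; /* f * D, mg */
        double tm = parms[N_FIXED + 3 * i + 2];
        double dt = t - t0;
        if (dt >= 0.0)
            ra += fD * dt / (tm * tm) * exp(-dt / tm);
    }
    return ra;
}

void derivsglucopa(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double AC = forc[0], ub = forc[1];
    double Q1 = y[0], Q2 = y[1], X = y[2], I = y[3], x1 = y[4], x2 = y[5];
    double Y = y[6], tPA = y[7], PAint = y[8], th = y[9], Z = y[10];
    double rGU = y[11], rGP = y[12], rdepl = y[13];
    double fAC, fh, fY, fdepl, q3, q4, tdepl, rm, Ra, disposal;

    if (ip[0] < 7) error("nout should be at least 7");

    Ra = meal_ra_total(*t);
    fAC = hill(AC, aAC, n2);
    fh  = hill(AC, ah, n2);
    fY  = hill(Y, aY, n1);

    {
        double fth = hill(th, tp, n2);
        q3 = (1.0 - fth) * q3l + fth * q3h;
        q4 = (1.0 - fth) * q4l + fth * q4h;
    }

    if (tPA < 0.5) {
        tdepl = bdepl;
    } else {
        tdepl = -adepl * (PAint / tPA) + bdepl;
        if (tdepl < 0.0) tdepl = 0.0;
    }
    fdepl = (tdepl <= 1e-9) ? (tPA > 0.0 ? 1.0 : 0.0) : hill(tPA, tdepl, n1);
    rm = beta * (q3 / q4 * Y + rGPb);

    ydot[0] = -(p1 + rGU - (rGP - rdepl) + (1.0 + Z) * X) * Q1
              - p4 * Q1 + p5 * Q2 + (p1 + Xb) * Q1b + Ra / BW;
    ydot[1] = p4 * Q1 - p5 * Q2;
    ydot[2] = -p2 * X + p3 * I;
    ydot[3] = k2 / (VI * BW) * x2 - k4 * I;
    ydot[4] = -k1 * x1 + ub;
    ydot[5] = k1 * x1 - (k2 + k3) * x2;
    ydot[6] = (AC - Y) / tauAC;
    ydot[7] = fAC - (1.0 - fAC) * tPA;
    ydot[8] = fAC * AC - (1.0 - fAC) * PAint;
    ydot[9] = fh - (1.0 - fh) * q5 * th;
    ydot[10] = bgain * fY * Y - (1.0 - fY) * Z / tauZ;
    ydot[11] = q1 * fY * Y - q2 * rGU;
    ydot[12] = q3 * fY * Y - q4 * rGP;
    ydot[13] = q6 * (fdepl * rm - rdepl);

    disposal = (p1 + (1.0 + Z) * X) * Q1;
    yout[0] = Q1 / Vg;                                           /* G mg/dl */
    yout[1] = Ra;                                                /* mg/min */
    yout[2] = AC;
    yout[3] = (p1 + Xb) * Q1b - alpha * disposal + (rGP - rdepl) * Q1; /* GP */
    yout[4] = (1.0 - alpha) * disposal + rGU * Q1;               /* GU */
    yout[5] = tdepl;
    yout[6] = ub;
}
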