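/* Mass-action right-hand side of the 14-species dimeric cyclase network,
 * plus a fixed-step (Euler) integrator with automatic sub-stepping.
 *
 * Species order (must match R):
 *  0 E, 1 EnG, 2 EGn, 3 EnA, 4 EAn, 5 EGG, 6 EGA, 7 EAG, 8 EAA,
 *  9 cdiA, 10 cdiG, 11 cAG, 12 A, 13 G
 *
 * Parameter order (length 16):
 *  0 k1A, 1 k2A, 2 k1G, 3 k2G, 4 kAG, 5 kGA        (on-rates, /uM/s)
 *  6 kn1A, 7 kn2A, 8 kn1G, 9 kn2G, 10 knAG, 11 knGA (off-rates, /s)
 *  12 kcat_cdiA, 13 kcat_cdiG, 14 kcat_cGAMP        (/s)
 *  15 homeostasis flag (0/1): clamp A and G (dA/dt = dG/dt = 0)
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define NSPEC 14
#define NPARM 16

static double parms[NPARM];

void cyclase_initparms(void (*odeparms)(int *, double *))
{
    int n = NPARM;
    odeparms(&n, parms);
}

static void cyclase_rhs(const double *y, const double *p, double *dy)
{
    const double E = y[0], EnG = y[1], EGn = y[2], EnA = y[3], EAn = y[4],
                 EGG = y[5], EGA = y[6], EAG = y[7], EAA = y[8],
                 A = y[12], G = y[13];
    const double k1A = p[0], k2A = p[1], k1G = p[2], k2G = p[3],
                 kAG = p[4], kGA = p[5],
                 kn1A = p[6], kn2A = p[7], kn1G = p[8], kn2G = p[9],
                 knAG = p[10], knGA = p[11],
                 kcA = p[12], kcG = p[13], kcAG = p[14];
    const int homeo = p[15] != 0.0;

    dy[0] = kn1G * EnG - k1G * E * G + kn1G * EGn - k1G * E * G
          + kn1A * EAn - k1A * E * A + kn1A * EnA - k1A * E * A
          + kcG * EGG + kcAG * EGA + kcA * EAA + kcAG * EAG;
    dy[1] = k1G * E * G - kn1G * EnG - k2G * EnG * G + kn2G * EGG
          + knAG * EAG - kAG * EnG * A;
    dy[2] = k1G * E * G - kn1G * EGn + kn2G * EGG - k2G * EGn * G
          + knAG * EGA - kAG * EGn * A;
    dy[3] = k1A * E * A - kn1A * EnA + knGA * EGA - kGA * EnA * G
          + kn2A * EAA - k2A * EnA * A;
    dy[4] = k1A * E * A - kn1A * EAn + kn2A * EAA - k2A * EAn * A
          + knGA * EAG - kGA * EAn * G;
    dy[5] = k2G * EnG * G - kn2G * EGG + k2G * EGn * G - kn2G * EGG
          - kcG * EGG;
    dy[6] = kAG * EGn * A - knAG * EGA + kGA * EnA * G - knGA * EGA
          - kcAG * EGA;
    dy[7] = kAG * EnG * A - knAG * EAG + kGA * EAn * G - knGA * EAG
          - kcAG * EAG;
    dy[8] = k2A * EnA * A - kn2A * EAA + k2A * EAn * A - kn2A * EAA
          - kcA * EAA;
    dy[9]  = kcA * EAA;
    dy[10] = kcG * EGG;
    dy[11] = kcAG * EAG + kcAG * EGA;

    if (homeo) {
        dy[12] = 0.0;
        dy[13] = 0.0;
    } else {
        dy[12] = -k1A * E * A + kn1A * EAn - k1A * E * A + kn1A * EnA
               - kAG * EGn * A + knAG * EGA - k2A * EnA * A + kn2A * EAA
               - k2A * EAn * A + kn2A * EAA - kAG * EnG * A + knAG * EAG;
        dy[13] = -k1G * E * G + kn1G * EnG - k1G * E * G + kn1G * EGn
               - k2G * EnG * G + kn2G * EGG - k2G * EGn * G + kn2G * EGG
               - kGA * EnA * G + knGA * EGA - kGA * EAn * G + knGA * EAG;
    }
}

/* deSolve-callable derivative */
void cyclase_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    cyclase_rhs(y, parms, ydot);
}

/* Largest per-species fractional outflow rate (1/s); bounds the stable
 * explicit step: dt * lambda_max <= safety guarantees no species loses
 * more than `safety` of itself in one update (hence stays non-negative). */
static double max_outflow_rate(const double *y, const double *p)
{
    const double A = y[12], G = y[13];
    const double k1A = p[0], k2A = p[1], k1G = p[2], k2G = p[3],
                 kAG = p[4], kGA = p[5],
                 kn1A = p[6], kn2A = p[7], kn1G = p[8], kn2G = p[9],
                 knAG = p[10], knGA = p[11],
                 kcA = p[12], kcG = p[13], kcAG = p[14];
    const int homeo = p[15] != 0.0;
    double lam, m = 0.0;

    lam = 2.0 * k1G * G + 2.0 * k1A * A;                 if (lam > m) m = lam;
    lam = kn1G + k2G * G + kAG * A;                      if (lam > m) m = lam;
    lam = kn1A + kGA * G + k2A * A;                      if (lam > m) m = lam;
    lam = 2.0 * kn2G + kcG;                              if (lam > m) m = lam;
    lam = knAG + knGA + kcAG;                            if (lam > m) m = lam;
    lam = 2.0 * kn2A + kcA;                              if (lam > m) m = lam;
    if (!homeo) {
        lam = 2.0 * k1A * y[0] + kAG * (y[1] + y[2]) + k2A * (y[3] + y[4]);
        if (lam > m) m = lam;
        lam = 2.0 * k1G * y[0] + k2G * (y[1] + y[2]) + kGA * (y[3] + y[4]);
        if (lam > m) m = lam;
    }
    return m;
}

/* Fixed-grid explicit Euler with automatic sub-stepping.  Records the state
 * at the requested reporting times; between reporting times it advances with
 * dt chosen so that dt * lambda_max <= safety. */
SEXP C_euler_timecourse(SEXP y0_, SEXP p_, SEXP times_, SEXP safety_,
                        SEXP max_substeps_)
{
    const double *y0 = REAL(y0_);
    const double *p = REAL(p_);
    const double *times = REAL(times_);
    const double safety = asReal(safety_);
    const double max_sub = asReal(max_substeps_);
    const int nt = LENGTH(times_);
    int i, j;

    if (LENGTH(y0_) != NSPEC) error("state vector must have %d entries", NSPEC);
    if (LENGTH(p_) != NPARM) error("parameter vector must have %d entries", NPARM);
    if (!(safety > 0.0 && safety < 1.0)) error("safety must be in (0, 1)");

    SEXP out_ = PROTECT(allocMatrix(REALSXP, nt, NSPEC));
    double *out = REAL(out_);
    double y[NSPEC], dy[NSPEC];

    for (j = 0; j < NSPEC; j++) y[j] = y0[j];
    for (j = 0; j < NSPEC; j++) out[0 + nt * j] = y[j];

    for (i = 1; i < nt; i++) {
        double t = times[i - 1];
        const double tend = times[i];
        double nsub = 0.0;
        while (t < tend) {
            const double lam = max_outflow_rate(y, p);
            double dt = tend - t;
            if (lam > 0.0 && dt > safety / lam) dt = safety / lam;
            cyclase_rhs(y, p, dy);
            for (j = 0; j < NSPEC; j++) y[j] += dt * dy[j];
            t += dt;
            nsub += 1.0;
            if (nsub > max_sub) {
                UNPROTECT(1);
                error("explicit update needs more than %.0f sub-steps in "
                      "[%g, %g] s; the system is too stiff for this mode",
                      max_sub, times[i - 1], tend);
            }
        }
        for (j = 0; j < NSPEC; j++) out[i + nt * j] = y[j];
    }

    UNPROTECT(1);
    return out_;
}

/* Plain derivative evaluation callable from R (used for cross-checks) */
SEXP C_cyclase_derivative(SEXP y_, SEXP p_)
{
    if (LENGTH(y_) != NSPEC) error("state vector must have %d entries", NSPEC);
    if (LENGTH(p_) != NPARM) error("parameter vector must have %d entries", NPARM);
    SEXP out_ = PROTECT(allocVector(REALSXP, NSPEC));
    cyclase_rhs(REAL(y_), REAL(p_), REAL(out_));
    UNPROTECT(1);
    return out_;
}

static const R_CallMethodDef call_entries[] = {
    {"C_euler_timecourse", (DL_FUNC) &C_euler_timecourse, 5},
    {"C_cyclase_derivative", (DL_FUNC) &C_cyclase_derivative, 2},
    {NULL, NULL, 0}
};

void R_init_gacakin(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE); /* deSolve looks up cyclase_derivs by name */
}
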