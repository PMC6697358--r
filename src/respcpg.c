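/* Compiled right-hand side of the reduced respiratory CPG network.
 *
 * Units are indexed 1..nu (1 pre-I, 2 early-I, 3 post-I, 4 aug-E, 5 PiCo).
 * Excitatory units carry a slow persistent-sodium inactivation state h;
 * inhibitory units carry an adaptation state p and either a dynamic h
 * (hmode = 1) or a quasi-steady h = hinf(V) (hmode = 0, the default,
 * which gives the 8-dimensional 4-unit network).
 *
 * Parameter vector layout (length 126, packed by pack_parms() in R --
 * the two must stay in sync):
 *   [0]      nu: number of units (4 or 5)
 *   [1]      hmode: 0 quasi-steady inhibitory h, 1 dynamic
 *   [2..15]  shared: C, ENa, EK, EsynE, EsynI, theta_h, sigma_h,
 *            theta_m, sigma_m, theta_n, sigma_n, eps, gsynE, gsynI
 *   [16+10u .. 25+10u] unit u = 0..4: exc flag, gNaP, gK, gL, EL,
 *            theta_out, sigma_out, tau_p, d_adapt, inh0
 *   [66+5i+j]  a[j+1, i+1]  excitatory weight, presyn j+1 -> postsyn i+1
 *   [91+5i+j]  b[j+1, i+1]  inhibitory weight
 *   [116..120] c1 tonic drives; [121..125] c2 tonic drives
 *
 * State layout: V[1..nu], then h for every h-carrying unit in unit
 * order, then p for inhibitory units in unit order.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPARMS 126

static double parms[NPARMS];

void respcpg_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

/* core evaluation against an explicit parameter vector */
static void eval_core(const double *p, const double *y, double *ydot,
                      double *fout, double *inhsum, double *excsum)
{
    const int nu = (int) p[0];
    const int hmode = (int) p[1];
    const double Cm = p[2], ENa = p[3], EK = p[4], EsynE = p[5], EsynI = p[6];
    const double th_h = p[7], sg_h = p[8], th_m = p[9], sg_m = p[10];
    const double th_n = p[11], sg_n = p[12], eps = p[13];
    const double gsynE = p[14], gsynI = p[15];

    int i, j;
    int exc[5];
    double V[5], h[5], pp[5];

    for (i = 0; i < nu; i++) {
        exc[i] = (int) p[16 + 10 * i];
        V[i] = y[i];
    }
    /* unpack h then p following the documented order */
    {
        int k = nu;
        for (i = 0; i < nu; i++) {
            if (exc[i] || hmode) h[i] = y[k++];
            else h[i] = 1.0 / (1.0 + exp((V[i] - th_h) / sg_h));
        }
        for (i = 0; i < nu; i++)
            if (!exc[i]) pp[i] = y[k++];
    }

    for (i = 0; i < nu; i++) {
        const double th_o = p[16 + 10 * i + 5], sg_o = p[16 + 10 * i + 6];
        fout[i] = 1.0 / (1.0 + exp((V[i] - th_o) / sg_o));
    }

    for (i = 0; i < nu; i++) {
        const double *up = p + 16 + 10 * i;
        const double gNaP = up[1], gK = up[2], gL = up[3], EL = up[4];
        const double inh0 = up[9];
        double isum = inh0, esum = p[116 + i] + p[121 + i];
        double minf, ninf, INaP, IK, IL, IsynI, IsynE;

        for (j = 0; j < nu; j++) {
            if (exc[j]) esum += p[66 + 5 * i + j] * fout[j];
            else        isum += p[91 + 5 * i + j] * fout[j];
        }
        inhsum[i] = isum;
        excsum[i] = esum;

        minf = 1.0 / (1.0 + exp((V[i] - th_m) / sg_m));
        INaP = gNaP * minf * h[i] * (V[i] - ENa);
        if (exc[i]) {
            ninf = 1.0 / (1.0 + exp((V[i] - th_n) / sg_n));
            IK = gK * ninf * ninf * ninf * ninf * (V[i] - EK);
        } else {
            IK = gK * pp[i] * (V[i] - EK);
        }
        IL = gL * (V[i] - EL);
        IsynI = gsynI * (V[i] - EsynI) * isum;
        IsynE = gsynE * (V[i] - EsynE) * esum;

        ydot[i] = -(INaP + IK + IL + IsynI + IsynE) / Cm;
    }

    {
        int k = nu;
        for (i = 0; i < nu; i++) {
            if (exc[i] || hmode) {
                const double hinf = 1.0 / (1.0 + exp((V[i] - th_h) / sg_h));
                const double tauh = eps / cosh((V[i] - th_h) / (2.0 * sg_h));
                ydot[k++] = (hinf - h[i]) / tauh;
            }
        }
        for (i = 0; i < nu; i++) {
            if (!exc[i]) {
                const double taup = p[16 + 10 * i + 7];
                const double dad = p[16 + 10 * i + 8];
                ydot[k++] = (dad * fout[i] - pp[i]) / taup;
            }
        }
    }
}

/* deSolve entry point; yout gets f_out, inh_sum, exc_sum per unit */
void respcpg_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const int nu = (int) parms[0];
    double fo[5], is[5], es[5];
    int i;
    eval_core(parms, y, ydot, fo, is, es);
    if (ip[0] >= 3 * nu) {
        for (i = 0; i < nu; i++) {
            yout[i] = fo[i];
            yout[nu + i] = is[i];
            yout[2 * nu + i] = es[i];
        }
    }
}

/* stateless .Call interface for direct evaluation / cross-checking */
SEXP respcpg_eval(SEXP sp, SEXP sy)
{
    const double *p = REAL(sp);
    const double *y = REAL(sy);
    const int nu = (int) p[0];
    const int ny = LENGTH(sy);
    SEXP ans, ydot, extra, names;
    double fo[5], is[5], es[5];
    int i;

    if (LENGTH(sp) != NPARMS)
        error("parameter vector must have length %d", NPARMS);

    PROTECT(ans = allocVector(VECSXP, 2));
    PROTECT(ydot = allocVector(REALSXP, ny));
    PROTECT(extra = allocVector(REALSXP, 3 * nu));
    eval_core(p, y, REAL(ydot), fo, is, es);
    for (i = 0; i < nu; i++) {
        REAL(extra)[i] = fo[i];
        REAL(extra)[nu + i] = is[i];
        REAL(extra)[2 * nu + i] = es[i];
    }
    SET_VECTOR_ELT(ans, 0, ydot);
    SET_VECTOR_ELT(ans, 1, extra);
    PROTECT(names = allocVector(STRSXP, 2));
    SET_STRING_ELT(names, 0, mkChar("ydot"));
    SET_STRING_ELT(names, 1, mkChar("extra"));
    setAttrib(ans, R_NamesSymbol, names);
    UNPROTECT(4);
    return ans;
}

static const R_CallMethodDef callMethods[] = {
    {"respcpg_eval", (DL_FUNC) &respcpg_eval, 2},
    {NULL, NULL, 0}
};

void R_init_respcpg(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, TRUE);
}
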