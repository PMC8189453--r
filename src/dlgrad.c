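/* Compiled right-hand side of the compartmental Dorsal/Cactus/Toll
 * reaction-diffusion network, in the form expected by deSolve
 * (initfunc + derivs with parameters passed through odeparms).
 *
 * State layout is compartment-major: y[9*j + s] for compartment j and
 * species s in the order cDl0, nDl0, Cf, DlC, T, DlCT, Cub, cDlstar,
 * nDlstar.  This keeps the Jacobian banded (bandwidth 9: reactions
 * couple species within a compartment, diffusion couples the same
 * species in adjacent compartments).
 */
#include <R.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 20

static double parms[N_PARMS];

#define K1  parms[0]
#define K2  parms[1]
#define K3  parms[2]
#define K4  parms[3]
#define K5  parms[4]
#define K6  parms[5]
#define K7  parms[6]
#define K8  parms[7]
#define K9  parms[8]
#define K10 parms[9]
#define K11 parms[10]
#define K12 parms[11]
#define D_DL  parms[12]
#define D_C   parms[13]
#define D_DLC parms[14]
#define NCOMP parms[15]
#define DX    parms[16]
#define SYN_DRIVER parms[17] /* 0 = k1*cDl0, 1 = k1*total cytoplasmic Dl */
#define K12_DEST   parms[18] /* 0 = nDlstar -> cDl0, 1 = nDlstar -> cDlstar */
#define TOLL_REC   parms[19] /* 0 = R9 releases T, 1 = Toll consumed */

void dlgrad_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void dlgrad_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const int n = (int) NCOMP;
    const double idx2 = 1.0 / (DX * DX);
    int j;

    for (j = 0; j < n; j++) {
        const double *s = y + 9 * j;
        double *d = ydot + 9 * j;
        const double cDl0 = s[0], nDl0 = s[1], Cf = s[2], DlC = s[3];
        const double T = s[4], DlCT = s[5], Cub = s[6];
        const double cDls = s[7], nDls = s[8];

        const double r3 = K3 * cDl0, r4 = K4 * nDl0;
        const double r5 = K5 * cDl0 * Cf, r6 = K6 * DlC;
        const double r7 = K7 * DlC * T, r8 = K8 * DlCT, r9 = K9 * DlCT;
        const double r10 = K10 * Cub, r11 = K11 * cDls, r12 = K12 * nDls;
        const double syn = (SYN_DRIVER > 0.5)
            ? K1 * (cDl0 + cDls + DlC + DlCT)
            : K1 * cDl0;

        d[0] = -r3 + r4 - r5 + r6;                  /* cDl0   */
        d[1] = r3 - r4;                             /* nDl0   */
        d[2] = syn - K2 * Cf - r5 + r6;             /* Cf     */
        d[3] = r5 - r6 - r7 + r8;                   /* DlC    */
        d[4] = -r7 + r8;                            /* T      */
        d[5] = r7 - r8 - r9;                        /* DlCT   */
        d[6] = r9 - r10;                            /* Cub    */
        d[7] = r9 - r11;                            /* cDl*   */
        d[8] = r11 - r12;                           /* nDl*   */

        if (TOLL_REC < 0.5) d[4] += r9;             /* T recycled by R9 */
        if (K12_DEST < 0.5) d[0] += r12; else d[7] += r12;
    }

    /* Fickian diffusion for cDl0 (s=0), Cf (s=2), DlC (s=3) with
     * reflective ghost compartments (zero flux at both midlines). */
    if (n > 1) {
        const double D[3] = { D_DL, D_C, D_DLC };
        const int sp[3] = { 0, 2, 3 };
        int k;
        for (k = 0; k < 3; k++) {
            const int s = sp[k];
            const double Dk = D[k] * idx2;
            for (j = 0; j < n; j++) {
                const double fm = (j == 0) ? y[9 * j + s] : y[9 * (j - 1) + s];
                const double fp = (j == n - 1) ? y[9 * j + s] : y[9 * (j + 1) + s];
                ydot[9 * j + s] += Dk * (fm - 2.0 * y[9 * j + s] + fp);
            }
        }
    }
}

static const R_CMethodDef cMethods[] = {
    {"dlgrad_initmod", (DL_FUNC) &dlgrad_initmod, 1},
    {"dlgrad_derivs",  (DL_FUNC) &dlgrad_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_dlgradient(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
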