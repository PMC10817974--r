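/* Compartmental ODE right-hand side for TCR-engineered T cell kinetics.
 *
 * Solved through deSolve's compiled-model interface (initfunc/derivs pair).
 * The parameter vector and state vector layouts must match tct_pack_params()
 * and tct_state_names() on the R side; the R reference implementation of the
 * same derivatives lives in R/model.R (tct_rhs) and the two are cross-checked
 * in the test suite.
 *
 * State layout (0-based):
 *   0 blood.scm   1 blood.cm   2 blood.em   3 blood.eff   4 blood.endo
 *   5 tdln.scm    6 tdln.cm    7 tdln.endo
 *   8 tissue.scm  9 tissue.cm 10 tissue.em 11 tissue.eff 12 tissue.endo
 *  13 tumor.em   14 tumor.eff
 *  15 antigen
 */

#include <R.h>

#define TCT_NPAR 45
#define TCT_NEQ  16

static double p[TCT_NPAR];

void tct_init(void (*odeparms)(int *, double *))
{
    int n = TCT_NPAR;
    odeparms(&n, p);
}

void tct_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double *kb  = p;        /* kprolif_base: scm cm em eff endo   */
    const double *ka  = p + 5;    /* kprolif_atg:  scm cm em eff        */
    const double *kc  = p + 9;    /* kconv:        scm cm em            */
    const double *kd  = p + 12;   /* kapop:        scm cm em eff endo   */
    const double *kt  = p + 17;   /* ktraffic:     scm cm em eff endo   */
    const double *kpd = p + 22;   /* Kp tdln:      scm cm endo          */
    const double *kps = p + 25;   /* Kp tissue:    scm cm em eff endo   */
    const double *kpu = p + 30;   /* Kp tumor:     em eff               */
    const double Vb = p[32], Vd = p[33], Vs = p[34], Vu = p[35];
    const double lamA = p[37], KA = p[38];
    const double *Tcap = p + 39;  /* blood tdln tissue tumor            */

    double A = y[15];
    double H = (A + KA > 0.0) ? A / (A + KA) : 0.0;

    double capb = 1.0 - (y[0] + y[1] + y[2] + y[3] + y[4]) / Tcap[0];
    double capd = 1.0 - (y[5] + y[6] + y[7]) / Tcap[1];
    double caps = 1.0 - (y[8] + y[9] + y[10] + y[11] + y[12]) / Tcap[2];
    double capu = 1.0 - (y[13] + y[14]) / Tcap[3];

    double f, Cb;
    int i;

    /* growth (logistic, antigen drive in tdln/tumour only) and apoptosis */
    for (i = 0; i < 5; i++)
        ydot[i] = (kb[i] * capb - kd[i]) * y[i];

    ydot[5] = ((kb[0] + ka[0] * H) * capd - kd[0]) * y[5];
    ydot[6] = ((kb[1] + ka[1] * H) * capd - kd[1]) * y[6];
    ydot[7] = (kb[4] * capd - kd[4]) * y[7];

    ydot[8]  = (kb[0] * caps - kd[0]) * y[8];
    ydot[9]  = (kb[1] * caps - kd[1]) * y[9];
    ydot[10] = (kb[2] * caps - kd[2]) * y[10];
    ydot[11] = (kb[3] * caps - kd[3]) * y[11];
    ydot[12] = (kb[4] * caps - kd[4]) * y[12];

    ydot[13] = ((kb[2] + ka[2] * H) * capu - kd[2]) * y[13];
    ydot[14] = ((kb[3] + ka[3] * H) * capu - kd[3]) * y[14];

    /* antigen-driven differentiation: scm->cm in TDLN, em->eff in tumour */
    f = kc[0] * H * y[5];
    ydot[5] -= f;
    ydot[6] += f;
    f = kc[2] * H * y[13];
    ydot[13] -= f;
    ydot[14] += f;

    /* trafficking: flux (cells/day) = kt * (C_blood*Kp - C_tissue) * V_tissue */
    Cb = y[0] / Vb; /* scm: tdln, tissue */
    f = kt[0] * (Cb * kpd[0] - y[5] / Vd) * Vd; ydot[5] += f; ydot[0] -= f;
    f = kt[0] * (Cb * kps[0] - y[8] / Vs) * Vs; ydot[8] += f; ydot[0] -= f;

    Cb = y[1] / Vb; /* cm: tdln, tissue */
    f = kt[1] * (Cb * kpd[1] - y[6] / Vd) * Vd; ydot[6] += f; ydot[1] -= f;
    f = kt[1] * (Cb * kps[1] - y[9] / Vs) * Vs; ydot[9] += f; ydot[1] -= f;

    Cb = y[2] / Vb; /* em: tissue, tumour */
    f = kt[2] * (Cb * kps[2] - y[10] / Vs) * Vs; ydot[10] += f; ydot[2] -= f;
    f = kt[2] * (Cb * kpu[0] - y[13] / Vu) * Vu; ydot[13] += f; ydot[2] -= f;

    Cb = y[3] / Vb; /* eff: tissue, tumour */
    f = kt[3] * (Cb * kps[3] - y[11] / Vs) * Vs; ydot[11] += f; ydot[3] -= f;
    f = kt[3] * (Cb * kpu[1] - y[14] / Vu) * Vu; ydot[14] += f; ydot[3] -= f;

    Cb = y[4] / Vb; /* endo: tdln, tissue */
    f = kt[4] * (Cb * kpd[2] - y[7] / Vd) * Vd; ydot[7] += f; ydot[4] -= f;
    f = kt[4] * (Cb * kps[4] - y[12] / Vs) * Vs; ydot[12] += f; ydot[4] -= f;

    ydot[15] = -lamA * A;
}
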