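#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void seq_init(void (*odeparms)(int *, double *));
void seq_rhs(int *neq, double *t, double *y, double *ydot,
             double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"seq_init", (DL_FUNC) &seq_init, 1},
    {"seq_rhs",  (DL_FUNC) &seq_rhs,  6},
    {NULL, NULL, 0}
};

void R_init_sfkin(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
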