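#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void initmod_mapk(void (*odeparms)(int *, double *));
void derivs_mapk(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip);

void R_init_mapkqb(DllInfo *dll)
{
    /* symbols are looked up by name from deSolve via dllname = "mapkqb" */
    R_registerRoutines(dll, NULL, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
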