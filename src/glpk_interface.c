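/* Thin .Call interface to the GNU Linear Programming Kit.
 *
 * Solves   max/min  c'x
 *          s.t.     rlb <= Ax <= rub
 *                   clb <=  x <= cub
 *          x_j binary for j in `binary` (1-based indices)
 *
 * A is passed in triplet form (ai, aj, ax), 1-based indices.
 * When `binary` is non-empty the problem is solved as a MIP with
 * GLPK's branch-and-cut (presolve enabled); otherwise plain simplex.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <glpk.h>
#include <math.h>

static void set_bounds(glp_prob *lp, int is_row, int idx, double lb, double ub)
{
    int type;
    int lb_fin = isfinite(lb), ub_fin = isfinite(ub);
    if (lb_fin && ub_fin)
        type = (lb == ub) ? GLP_FX : GLP_DB;
    else if (lb_fin)
        type = GLP_LO;
    else if (ub_fin)
        type = GLP_UP;
    else
        type = GLP_FR;
    if (is_row)
        glp_set_row_bnds(lp, idx, type, lb, ub);
    else
        glp_set_col_bnds(lp, idx, type, lb, ub);
}

SEXP C_glpk_solve(SEXP s_obj, SEXP s_maximize,
                  SEXP s_nrow,
                  SEXP s_ai, SEXP s_aj, SEXP s_ax,
                  SEXP s_rlb, SEXP s_rub,
                  SEXP s_clb, SEXP s_cub,
                  SEXP s_binary)
{
    const int n = LENGTH(s_obj);
    const int m = asInteger(s_nrow);
    const int nnz = LENGTH(s_ax);
    const int nbin = LENGTH(s_binary);
    const double *obj = REAL(s_obj);
    const double *rlb = REAL(s_rlb), *rub = REAL(s_rub);
    const double *clb = REAL(s_clb), *cub = REAL(s_cub);
    int i, status;
    double objval = NA_REAL;

    glp_term_out(GLP_OFF);
    glp_prob *lp = glp_create_prob();
    glp_set_obj_dir(lp, asLogical(s_maximize) ? GLP_MAX : GLP_MIN);

    if (m > 0) glp_add_rows(lp, m);
    glp_add_cols(lp, n);
    for (i = 1; i <= m; i++)
        set_bounds(lp, 1, i, rlb[i - 1], rub[i - 1]);
    /* set kinds before bounds: GLP_BV resets bounds to [0, 1] */
    for (i = 0; i < nbin; i++)
        glp_set_col_kind(lp, INTEGER(s_binary)[i], GLP_BV);
    for (i = 1; i <= n; i++) {
        set_bounds(lp, 0, i, clb[i - 1], cub[i - 1]);
        glp_set_obj_coef(lp, i, obj[i - 1]);
    }

    /* GLPK wants 1-based arrays with a dummy element at position 0 */
    {
        int *ia = (int *) R_alloc(nnz + 1, sizeof(int));
        int *ja = (int *) R_alloc(nnz + 1, sizeof(int));
        double *ar = (double *) R_alloc(nnz + 1, sizeof(double));
        for (i = 0; i < nnz; i++) {
            ia[i + 1] = INTEGER(s_ai)[i];
            ja[i + 1] = INTEGER(s_aj)[i];
            ar[i + 1] = REAL(s_ax)[i];
        }
        glp_load_matrix(lp, nnz, ia, ja, ar);
    }

    SEXP s_x = PROTECT(allocVector(REALSXP, n));
    for (i = 0; i < n; i++) REAL(s_x)[i] = NA_REAL;

    glp_scale_prob(lp, GLP_SF_AUTO);

    if (nbin == 0) {
        glp_smcp parm;
        glp_init_smcp(&parm);
        parm.msg_lev = GLP_MSG_OFF;
        parm.presolve = GLP_OFF;
        int ret = glp_simplex(lp, &parm);
        status = (ret == 0) ? glp_get_status(lp) : GLP_UNDEF;
        if (status == GLP_OPT) {
            objval = glp_get_obj_val(lp);
            for (i = 1; i <= n; i++)
                REAL(s_x)[i - 1] = glp_get_col_prim(lp, i);
        }
    } else {
        /* solve the LP relaxation with simplex, then branch-and-cut;
         * glp_intopt's own presolver is avoided deliberately */
        glp_smcp sparm;
        glp_init_smcp(&sparm);
        sparm.msg_lev = GLP_MSG_OFF;
        int sret = glp_simplex(lp, &sparm);
        int sstat = (sret == 0) ? glp_get_status(lp) : GLP_UNDEF;
        if (sstat != GLP_OPT) {
            status = sstat;
        } else {
            glp_iocp parm;
            glp_init_iocp(&parm);
            parm.msg_lev = GLP_MSG_OFF;
            parm.presolve = GLP_OFF;
            parm.tm_lim = 180000; /* fail loudly rather than hang */
            int ret = glp_intopt(lp, &parm);
            status = glp_mip_status(lp);
            if (ret == GLP_ENOPFS || ret == GLP_ENODFS)
                status = GLP_NOFEAS;
        }
        if (status == GLP_OPT || status == GLP_FEAS) {
            status = (status == GLP_FEAS) ? GLP_UNDEF : GLP_OPT;
            if (status == GLP_OPT) {
                objval = glp_mip_obj_val(lp);
                for (i = 1; i <= n; i++)
                    REAL(s_x)[i - 1] = glp_mip_col_val(lp, i);
            }
        }
    }

    glp_delete_prob(lp);

    SEXP res = PROTECT(allocVector(VECSXP, 3));
    SEXP nms = PROTECT(allocVector(STRSXP, 3));
    SET_STRING_ELT(nms, 0, mkChar("status"));
    SET_STRING_ELT(nms, 1, mkChar("objval"));
    SET_STRING_ELT(nms, 2, mkChar("x"));
    setAttrib(res, R_NamesSymbol, nms);
    SET_VECTOR_ELT(res, 0, ScalarInteger(status));
    SET_VECTOR_ELT(res, 1, ScalarReal(objval));
    SET_VECTOR_ELT(res, 2, s_x);
    UNPROTECT(3);
    return res;
}

static const R_CallMethodDef call_methods[] = {
    {"C_glpk_solve", (DL_FUNC) &C_glpk_solve, 11},
    {NULL, NULL, 0}
};

void R_init_ecgem(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_methods, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
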