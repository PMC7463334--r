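#' Adaptive-genotype probability from a fitted association model
#'
#' Inverse-logit of `alpha + beta * env (+ gamma * covariate)`. At
#' prediction time the structure covariate is held at a constant (its
#' sample mean, i.e. 0 after centering) because spatial covariate values
#' are undefined for unsampled reefs.
#'
#' @param sgea one SGEA row (or any list with `alpha`, `beta` and optional
#'   `gamma*` entries).
#' @param env_value environmental value(s).
#' @param covariate_value constant covariate value(s), recycled across the
#'   gamma coefficients.
#' @return probabilities in `[0, 1]`; missing env gives missing.
#' @export
genotype_probability <- function(sgea, env_value, covariate_value = 0) {
  eta <- sgea$alpha + sgea$beta * env_value
  gammas <- unlist(sgea[grep("^gamma", names(sgea))])
  gammas <- gammas[!is.na(gammas)]
  if (length(gammas))
    eta <- eta + sum(gammas * rep_len(covariate_value, length(gammas)))
  stats::plogis(eta)
}

#' Probability of carrying adaptive genotypes (PA)
#'
#' Applies each retained SGEA's logistic model to its environmental
#' variable at every reef cell and averages the per-genotype probabilities
#' arithmetically. The SGEA subset is selectable (e.g. the heat-stress
#' subset: the BAF-related associations with coherent annotations).
#'
#' @param sgea_set data frame of SGEAs (rows from [select_sgea()]).
#' @param env_table data frame of environmental values (reef cells x
#'   variables); every SGEA's `env` must be one of its columns.
#' @param subset optional logical or integer index selecting SGEAs.
#' @param covariate_value constant at which structure covariates are held.
#' @return data frame with `cell`, `PA`, and one probability column per
#'   contributing SGEA.
#' @export
compute_pa <- function(sgea_set, env_table, subset = NULL,
                       covariate_value = 0) {
  if (!is.null(subset)) sgea_set <- sgea_set[subset, , drop = FALSE]
  if (!nrow(sgea_set)) stop("empty SGEA set")
  missing_env <- setdiff(sgea_set$env, names(env_table))
  if (length(missing_env))
    stop("environmental variable(s) not in table: ",
         paste(missing_env, collapse = ", "))
  probs <- sapply(seq_len(nrow(sgea_set)), function(i)
    genotype_probability(as.list(sgea_set[i, ]),
                         env_table[[sgea_set$env[i]]], covariate_value))
  probs <- matrix(probs, nrow = nrow(env_table))
  colnames(probs) <- sprintf("p_%s_%s", sgea_set$snp, sgea_set$class)
  data.frame(cell = rownames(env_table) %||% seq_len(nrow(env_table)),
             PA = rowMeans(probs), probs, check.names = FALSE)
}
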