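#' Specify the multi-environment mixed model
#'
#' Describes the variance structure of the plot-level model
#' y = X tau + Z u + Z_g g + e: the genotype-by-environment genetic term
#' (diagonal or factor-analytic across environments, identity across lines),
#' an optional replicate-within-environment random term, and the residual
#' (independent, or separable AR1xAR1 over the field row/column grid with an
#' environment-specific variance).
#'
#' @param genetic `"diag"` or `"fa"`.
#' @param fa_k factor-analytic order (>= 1, < number of environments); only
#'   used when `genetic = "fa"`.
#' @param residual `"iid"` or `"ar1"`.
#' @param rep_effect include a replicate-within-environment random intercept
#'   with a single scalar variance.
#' @param row_col_trends add fixed linear row and column trends per
#'   environment.
#' @return A `model_spec` object.
#' @export
model_spec <- function(genetic = c("diag", "fa"), fa_k = 1L,
                       residual = c("iid", "ar1"), rep_effect = TRUE,
                       row_col_trends = FALSE) {
  genetic <- match.arg(genetic)
  residual <- match.arg(residual)
  if (genetic == "fa" && fa_k < 1L) stop("fa_k must be >= 1")
  structure(list(genetic = genetic, fa_k = as.integer(fa_k),
                 residual = residual, rep_effect = isTRUE(rep_effect),
                 row_col_trends = isTRUE(row_col_trends)),
            class = "model_spec")
}

#' Assemble the design bundle for the multi-environment mixed model
#'
#' Orders plots by (environment, row, column) so residual blocks are
#' separable, builds the fixed matrix (per-environment intercepts, one fixed
#' column per control line, optional linear row/column trends), the genetic
#' incidence matrix (test lines only; environment-major column order), and the
#' replicate-within-environment incidence.
#'
#' Lines present in the genotype set enter the random genetic term; any other
#' line in the phenotype table is treated as a control and receives its own
#' fixed-effect column.
#'
#' @param phenotypes plot-level data.frame with columns `env`, `line`, `rep`,
#'   `row`, `col` and the trait column.
#' @param trait name of the trait column to model.
#' @param geno_lines character vector of genotyped (test) line ids.
#' @param spec a [model_spec()].
#' @param keep_envs optional subset of environments to retain.
#' @return A `met_design` list bundling the response, design matrices and
#'   index maps; consumed by [reml_fit()] and [genome_scan()].
#' @export
build_design <- function(phenotypes, trait, geno_lines, spec = model_spec(),
                         keep_envs = NULL) {
  need <- c("env", "line", "rep", "row", "col", trait)
  miss <- setdiff(need, names(phenotypes))
  if (length(miss)) stop("phenotypes lack columns: ", paste(miss, collapse = ", "))
  ph <- phenotypes[!is.na(phenotypes[[trait]]), need]
  if (!is.null(keep_envs)) ph <- ph[ph$env %in% keep_envs, , drop = FALSE]
  if (nrow(ph) == 0L) stop("no non-missing observations for trait ", trait)
  dup <- duplicated(ph[c("env", "row", "col")])
  if (any(dup)) stop("duplicate (env, row, col) plot coordinates")
  ph <- ph[order(ph$env, ph$row, ph$col), , drop = FALSE]

  envs <- unique(ph$env)
  J <- length(envs)
  env_idx <- match(ph$env, envs)
  lines <- as.character(geno_lines)
  m <- length(lines)
  is_test <- ph$line %in% lines
  controls <- sort(unique(ph$line[!is_test]))
  n <- nrow(ph)
  cnt <- table(factor(ph$env, levels = envs))
  if (any(cnt < 2L)) stop("every environment needs at least 2 observations")

  # fixed part: env intercepts, control columns, optional row/col trends
  X <- matrix(0, n, J, dimnames = list(NULL, paste0("env:", envs)))
  X[cbind(seq_len(n), env_idx)] <- 1
  term_of <- rep("env", J)
  for (cl in controls) {
    X <- cbind(X, as.numeric(ph$line == cl))
    colnames(X)[ncol(X)] <- paste0("control:", cl)
    term_of <- c(term_of, "control")
  }
  if (spec$row_col_trends) {
    for (j in seq_len(J)) {
      e <- env_idx == j
      for (w in c("row", "col")) {
        v <- numeric(n)
        v[e] <- scale(ph[[w]][e])
        if (stats::sd(v[e]) > 0) {
          X <- cbind(X, v)
          colnames(X)[ncol(X)] <- paste0("trend:", envs[j], ":", w)
          term_of <- c(term_of, "trend")
        }
      }
    }
  }

  # genetic incidence: environment-major, q_g = J * m columns
  line_idx <- match(ph$line, lines)
  gi <- which(is_test)
  Zg <- Matrix::sparseMatrix(i = gi,
                             j = (env_idx[gi] - 1L) * m + line_idx[gi],
                             x = 1, dims = c(n, J * m))
  Zu <- NULL
  if (spec$rep_effect) {
    repf <- factor(paste(ph$env, ph$rep, sep = ":"))
    Zu <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(repf), x = 1,
                               dims = c(n, nlevels(repf)))
  }
  Z <- if (is.null(Zu)) Zg else cbind(Zg, Zu)

  # per-environment grid geometry for the AR1xAR1 residual
  grid <- lapply(seq_len(J), function(j) {
    e <- env_idx == j
    r <- ph$row[e]; cc <- ph$col[e]
    ur <- sort(unique(r)); uc <- sort(unique(cc))
    complete <- sum(e) == length(ur) * length(uc)
    list(rows = r, cols = cc, urows = ur, ucols = uc, complete = complete)
  })

  structure(list(y = ph[[trait]], X = X, term_of = term_of, Z = Z,
                 q_g = J * m, q_u = if (is.null(Zu)) 0L else ncol(Zu),
                 env_idx = env_idx, envs = envs, n_env = J,
                 lines = lines, n_lines = m, line_idx = line_idx,
                 is_test = is_test, grid = grid, plots = ph,
                 trait = trait, spec = spec,
                 cache = new.env(parent = emptyenv())),
            class = "met_design")
}

#' @export
print.met_design <- function(x, ...) {
  cat(sprintf(paste0("MET design: %d plots, %d environments, %d test lines, ",
                     "%d control(s), %d fixed columns\n"),
              length(x$y), x$n_env, x$n_lines,
              sum(x$term_of == "control"), ncol(x$X)))
  invisible(x)
}
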