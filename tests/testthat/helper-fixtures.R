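# Fixtures are built in code; nothing is stored on disk.

# small count matrix with a known housekeeping set
with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

toy_count_matrix <- function(n_genes = 30, n_hk = 4, n_cols = 6, mu = 200,
                             size = 10, seed = 1) with_test_seed(seed, {
  genes <- c(sprintf("G%03d", seq_len(n_genes)), sprintf("HK%02d", seq_len(n_hk)))
  cols <- sprintf("S%02d_Control", seq_len(n_cols))
  m <- matrix(rnbinom(length(genes) * n_cols, mu = mu, size = size),
              length(genes), n_cols, dimnames = list(genes, cols))
  count_matrix(m, housekeeping = grep("^HK", genes, value = TRUE))
})

# NB matrix with two groups and an optional planted fold change
nb_group_matrix <- function(n_genes, n_a, n_b, mu = 200, size = 10,
                            planted = integer(), effect = 2,
                            seed = 1) with_test_seed(seed, {
  genes <- sprintf("G%04d", seq_len(n_genes))
  ca <- sprintf("A%02d_Control", seq_len(n_a))
  cb <- sprintf("B%02d_Control", seq_len(n_b))
  mu_mat <- matrix(mu, n_genes, n_a + n_b)
  if (length(planted)) mu_mat[planted, n_a + seq_len(n_b)] <- mu * effect
  m <- matrix(rnbinom(length(mu_mat), mu = as.vector(mu_mat), size = size),
              n_genes, n_a + n_b, dimnames = list(genes, c(ca, cb)))
  list(cm = count_matrix(m, housekeeping = character()),
       group_a = ca, group_b = cb, genes = genes)
})

# cell table with known geometry
toy_cells <- function(cd8 = NULL, foxp3 = NULL, panck = NULL, other = NULL) {
  mk <- function(m, ph) if (is.null(m)) NULL else
    data.frame(x_um = m[, 1], y_um = m[, 2], phenotype = ph)
  do.call(rbind, Filter(Negate(is.null), list(
    mk(panck, "panCK"), mk(cd8, "CD8"), mk(foxp3, "FoxP3"), mk(other, "other"))))
}

# single-class cohort config used by the spatial and recovery tests
one_class_config <- function(class, seed, n_samples = 1, ...) {
  props <- setNames(rep(0, 5), c("R", "M_a", "M_b", "M_c", "NR"))
  props[class] <- 1
  cohort_config(n_samples = n_samples, class_proportions = props, seed = seed, ...)
}

expect_rel_equal <- function(x, y, tol = 1e-9) {
  expect_lt(max(abs(x - y) / pmax(1, abs(y))), tol)
}
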