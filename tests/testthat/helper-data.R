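# fixtures are built in code; nothing is read from disk

make_labels <- function(m, gene_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(m)
  gene_ids <- gene_ids %||% paste0("g", seq_len(nrow(m)))
  sample_ids <- sample_ids %||% paste0("s", seq_len(ncol(m)))
  out <- tibble::tibble(gene_id = gene_ids)
  for (j in seq_along(sample_ids)) out[[sample_ids[j]]] <- m[, j]
  out
}

make_groups <- function(group, sample_ids = NULL) {
  sample_ids <- sample_ids %||% paste0("s", seq_along(group))
  tibble::tibble(sample_id = sample_ids, group = as.character(group))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# four-sample toy from the counting contract: geneX labelled (+1,+1,-1,0),
# samples split case/case/ctrl/ctrl
toy_labels <- function() make_labels(matrix(c(1L, 1L, -1L, 0L), nrow = 1),
  gene_ids = "geneX"
)
toy_groups <- function() make_groups(c("case", "case", "ctrl", "ctrl"))

# a random labelled dataset + random two-class assignment
random_dataset <- function(n_genes, n_samples, seed,
                           levels = c(-1L, 0L, 1L)) {
  withr::with_seed(seed, {
    m <- matrix(sample(levels, n_genes * n_samples, replace = TRUE),
      nrow = n_genes
    )
    grp <- sample(rep(c("case", "ctrl"), length.out = n_samples))
    list(labels = make_labels(m), groups = make_groups(grp))
  })
}

# printed reference critical values for the null confidence at n = 1000:
# blocks by p2, rows by level (80/90/95/99%), columns by p1 = .1 .3 .5 .7 .9
printed_critical_values <- function() {
  vals <- c(
    # p2 = 0.1
    .1245, .1135, .1105, .1095, .1075,
    .1395, .1225, .1165, .1145, .1125,
    .1515, .1285, .1225, .1185, .1165,
    .1755, .1415, .1315, .1265, .1235,
    # p2 = 0.3
    .3385, .3215, .3165, .3145, .3125,
    .3585, .3335, .3255, .3215, .3195,
    .3755, .3435, .3335, .3285, .3245,
    .4095, .3625, .3475, .3405, .3355,
    # p2 = 0.5
    .5415, .5235, .5185, .5155, .5135,
    .5635, .5365, .5285, .5235, .5205,
    .5825, .5475, .5365, .5305, .5265,
    .6165, .5665, .5515, .5435, .5385,
    # p2 = 0.7
    .7385, .7215, .7165, .7145, .7125,
    .7585, .7335, .7255, .7215, .7195,
    .7745, .7425, .7325, .7275, .7245,
    .8035, .7605, .7465, .7395, .7345,
    # p2 = 0.9
    .9255, .9145, .9105, .9095, .9075,
    .9375, .9215, .9165, .9135, .9125,
    .9465, .9275, .9215, .9175, .9155,
    .9635, .9375, .9295, .9255, .9225
  )
  grid <- tidyr::expand_grid(
    p2 = c(.1, .3, .5, .7, .9),
    level = c(.80, .90, .95, .99),
    p1 = c(.1, .3, .5, .7, .9)
  )
  grid$c_min <- vals
  grid
}

mine_quiet <- function(...) suppressMessages(mine_rules(...))
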