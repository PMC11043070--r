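# Small builders shared across test files.

tiny_cell_table <- function(n = 3, channels = c("pomc", "glipr1")) {
  tbl <- tibble::tibble(
    cell_id = sprintf("c%02d", seq_len(n)),
    animal_id = "a1",
    section_id = "s1",
    group = "CD",
    x = runif(n, 0, 100), y = runif(n, 0, 100), z = runif(n, 0, 20),
    size = runif(n, 50, 150),
    lineage_positive = TRUE
  )
  for (ch in channels) {
    tbl[[paste0("mean_", ch)]] <- runif(n, 0, 100)
    tbl[[paste0("max_", ch)]] <- tbl[[paste0("mean_", ch)]] + runif(n, 0, 50)
  }
  tbl
}

# Brute-force per-voxel quantification oracle: mean/max per label id,
# computed with plain loops over the label array.
brute_force_quantify <- function(arr, labels) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  do.call(rbind, lapply(ids, function(id) {
    v <- arr[labels == id]
    data.frame(label = id, mean = mean(v), max = max(v))
  }))
}

# Brute-force KDE oracle: direct triple-product kernel sum at given nodes.
brute_force_kde <- function(pts, nodes, bw) {
  apply(nodes, 1, function(g) {
    mean(dnorm((g[1] - pts[, 1]) / bw[1]) / bw[1] *
           dnorm((g[2] - pts[, 2]) / bw[2]) / bw[2] *
           dnorm((g[3] - pts[, 3]) / bw[3]) / bw[3])
  })
}

fig4_fixture <- function(seed, panel = paste0("pomcgene", 1:10)) {
  gen_count_matrix(
    list(a = c(CD = 25, HFD = 20), b = c(CD = 6, HFD = 7),
         c = c(CD = 5, HFD = 7), d = c(CD = 2, HFD = 4)),
    n_genes = 200,
    pomc_program = list(genes = panel, depleted_in = c("c", "d"),
                        depletion_fold = 4),
    seed = seed
  )
}
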