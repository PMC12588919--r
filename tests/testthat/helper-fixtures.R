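# leaf_A: a hand-laid-out clean leaf whose vein lengths are Pythagorean
# triples (L1 = 10, L2 = 5, L3 = 3, L4 = 2.5, L5 = 1) and whose polygon
# cycles are simple under the default polygon_config.
leaf_A <- rbind(
  c(-1.50, -0.40),  # 1  left proximal vein base
  c(-0.50,  0.00),  # 2  prox/dist shared base
  c(-0.20,  0.00),  # 3  dist/mid shared base
  c( 0.20,  0.00),  # 4  right midvein base
  c(-2.00, -0.20),  # 5  distal base of petiolar vein
  c(-1.00, -0.30),  # 6  proximal base of petiolar vein
  c(-1.60,  0.15),  # 7  proximal vein width point
  c(-1.90,  1.70),  # 8  distal base of distal-vein branch
  c(-1.30,  1.20),  # 9  proximal base of distal-vein branch
  c(-1.50,  1.90),  # 10 distal vein width point
  c(-0.10,  6.40),  # 11 distal base of midvein branch
  c(-0.12,  5.60),  # 12 proximal base of midvein branch
  c( 0.12,  6.00),  # 13 midvein width point
  c(-1.80, -0.90),  # 14 tip of petiolar vein
  c(-3.40,  0.50),  # 15 tip of proximal lobe
  c(-2.60,  1.20),  # 16 proximal sinus
  c(-2.90,  1.80),  # 17 tip of distal vein branch
  c(-3.35,  4.00),  # 18 tip of distal lobe
  c(-2.00,  4.60),  # 19 distal sinus
  c(-1.50,  6.00),  # 20 tip of midvein branch
  c( 0.00, 10.00))  # 21 leaf tip

# wrap point matrices into a one-row (or stacked) landmark data frame
make_leaf_df <- function(points_list, genotype = NULL, position = "middle",
                         daylength = 14L, year = 2021L,
                         presentation = "own_rooted") {
  if (is.matrix(points_list)) points_list <- list(points_list)
  n <- length(points_list)
  rows <- lapply(seq_len(n), function(i) {
    p <- points_list[[i]]
    data.frame(leaf_id = paste0("leaf_", i),
               genotype_id = (genotype %||% paste0("g", i))[min(i, length(genotype %||% i))],
               presentation = presentation, position = position,
               daylength_h = daylength, year = year,
               t(as.vector(t(p))), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df) <- c("leaf_id", "genotype_id", "presentation", "position",
                 "daylength_h", "year",
                 as.vector(rbind(paste0("x", 1:21), paste0("y", 1:21))))
  as_landmark_df(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a fully crossed per-leaf trait table with deterministic values, for
# trait-matrix assembly tests
make_factorial_traits <- function(n_genotypes, positions = c("apical", "middle", "basal"),
                                  daylengths = c(14L, 13L), years = c(2021L, 2022L),
                                  presentation = "own_rooted") {
  grid <- expand.grid(genotype_id = sprintf("g%03d", seq_len(n_genotypes)),
                      position = positions, daylength_h = daylengths,
                      year = years, stringsAsFactors = FALSE)
  tr <- matrix(seq_len(nrow(grid) * 16) / 7, nrow(grid), 16,
               dimnames = list(NULL, trait_names()))
  cbind(data.frame(leaf_id = sprintf("leaf%05d", seq_len(nrow(grid))),
                   grid[, 1, drop = FALSE], presentation = presentation,
                   grid[, -1], stringsAsFactors = FALSE),
        as.data.frame(tr))
}

# small simulated cross shared by scan tests
make_test_cross <- function(n = 120, n_lgs = 3, markers = 15, seed = 99) {
  map <- simulate_map(n_lgs, markers, 80)
  simulate_genotypes(n, map, seed = seed)
}
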