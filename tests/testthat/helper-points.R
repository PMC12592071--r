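# build a seed_points tibble directly from coordinates
as_seed_points <- function(x, y, dim_hw = c(400L, 400L), grid = 40L,
                           seed = 0L) {
  tbl <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        visited = FALSE)
  structure(tbl, rng_seed = as.integer(seed),
            image_dim = as.integer(dim_hw), grid = as.integer(grid),
            class = c("seed_points", class(tbl)))
}

# plant_skeleton from a list of n x 2 keypoint matrices (tip first)
as_skeleton <- function(leaves, view = "top", pot = NULL, reference = NULL) {
  empty <- tibble::tibble(leaf_id = integer(), vertex = integer(),
                          x = numeric(), y = numeric())
  df <- dplyr::bind_rows(empty, lapply(seq_along(leaves), function(i) {
    P <- leaves[[i]]
    tibble::tibble(leaf_id = i, vertex = seq_len(nrow(P)),
                   x = P[, 1], y = P[, 2])
  }))
  structure(list(leaves = df, view = view, pot = pot,
                 reference = reference, params = NULL),
            class = "plant_skeleton")
}

# random distinct integer point set in a small box
random_point_set <- function(n, box = 60L) {
  repeat {
    xy <- cbind(sample.int(box, n, replace = TRUE),
                sample.int(box, n, replace = TRUE))
    if (nrow(unique(xy)) == n) return(xy)
  }
}
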