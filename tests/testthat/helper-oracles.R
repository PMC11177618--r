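## Independent oracles used across tests. These deliberately use naive
## algorithms (dense matrices, label propagation) distinct from the
## package's implementations.

## connected components by min-label propagation on a dense adjacency
## matrix; returns a list of sorted linear-index vectors
oracle_components <- function(lin, shape, adjacency = 6) {
  n <- length(lin)
  if (!n) return(list())
  ijk <- arrayInd(lin, .dim = shape)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- abs(ijk[i, ] - ijk[j, ])
    if (any(d > 1)) next
    s <- sum(d)
    adj[i, j] <- switch(as.character(adjacency),
                        "6" = s == 1, "18" = s <= 2, "26" = TRUE)
  }
  lab <- seq_len(n)
  repeat {
    new <- lab
    for (i in seq_len(n)) {
      nb <- lab[adj[i, ]]
      if (length(nb)) new[i] <- min(new[i], min(nb))
    }
    if (identical(new, lab)) break
    lab <- new
  }
  unname(lapply(split(seq_len(n), lab), function(ix) sort(lin[ix])))
}

## canonical form for comparing component partitions
canon_components <- function(comps) {
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[`, 0L, 1))]
}

## dense O(V^2) connectedness oracle: full correlation matrix row means
## (self excluded), Fisher z after averaging
oracle_connectedness <- function(run, voxels) {
  keep <- setdiff(seq_len(dim(run$data)[4]), run$censored_frames)
  M <- matrix(run$data, prod(dim(run$data)[1:3]), dim(run$data)[4])
  X <- t(M[voxels, keep, drop = FALSE])
  R <- stats::cor(X)
  atanh((rowSums(R) - 1) / (ncol(R) - 1))
}

## quick run builder: data from a frames x voxels matrix on a tiny grid
run_from_matrix <- function(X, shape, tr_s = 1, censored = integer(0),
                            subject_id = NA, condition = NA) {
  stopifnot(ncol(X) == prod(shape))
  bold_run(array(t(X), c(shape, nrow(X))), vol_geometry(shape),
           tr_s = tr_s, censored_frames = censored,
           subject_id = subject_id, condition = condition)
}
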