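#' Cluster-atomic group-shuffle split
#'
#' Partitions records into token-training, binary-training and
#' evaluation sets (default fractions 0.7 / 0.2 / 0.1) such that no
#' sequence cluster spans two sets — the guard against inflated
#' evaluation scores through near-duplicate sequences. Whole clusters
#' are assigned greedily in seeded shuffled order: each cluster goes
#' to the split with the largest remaining record-count quota
#' (earlier split on ties), quotas being the largest-remainder
#' apportionment of the fractions. Deterministic for a fixed seed.
#'
#' @param ids character vector of record ids
#' @param cluster_map named character vector: cluster id per record id
#'   (every record must be assigned)
#' @param fractions length-3 numeric summing to 1
#' @param seed integer seed
#' @return list with character-vector elements `token_train`,
#'   `binary_train`, `eval`
#' @export
group_shuffle_split <- function(ids, cluster_map,
                                fractions = c(0.7, 0.2, 0.1),
                                seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three numbers summing to 1")
  missing <- setdiff(ids, names(cluster_map))
  if (length(missing))
    stop("record(s) with no cluster assignment: ",
         paste(missing, collapse = ", "))
  cl <- cluster_map[ids]
  n <- length(ids)
  # largest-remainder quotas over record counts
  raw <- fractions * n
  quota <- floor(raw)
  rem <- n - sum(quota)
  if (rem > 0) {
    extra <- order(raw - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1
  }
  members <- split(ids, cl)
  set.seed(seed)
  ord <- sample(length(members))
  assign <- integer(length(members))
  deficit <- quota
  for (j in ord) {
    pick <- which.max(deficit)  # ties -> earliest split
    assign[j] <- pick
    deficit[pick] <- deficit[pick] - length(members[[j]])
  }
  if (length(members) == 1L && n > 1L)
    warning("all records belong to a single cluster; ",
            "the entire dataset lands in one split")
  out <- lapply(1:3, function(k) {
    v <- unlist(members[assign == k], use.names = FALSE)
    if (is.null(v)) character(0) else v[order(match(v, ids))]
  })
  names(out) <- c("token_train", "binary_train", "eval")
  out
}
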