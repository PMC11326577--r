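#' Curation configuration
#'
#' All printed constants of the training-set curation pipeline in one
#' place. Defaults: minimum protein length 200 aa (shorter sequences
#' are discarded — the minimum length at which depolymerase domains
#' are expected); profile-search hits require bit score strictly
#' above 20 with at least 30 aligned positions; structural hits
#' require match probability strictly above 0.5, relaxed to strictly
#' above 0.2 for the right-handed beta-helix (the most divergent
#' fold); at most 5 proteins kept per (cluster, annotation) pair.
#' The sequence-clustering constants (CD-HIT 95% identity / 80%
#' coverage, affinity-propagation damping 0.90 with no preference,
#' MMseqs profile-construction flags) are recorded here for
#' provenance; those external tools are consumed through their output
#' files, never executed by this package.
#'
#' @param min_length minimum sequence length kept (inclusive)
#' @param min_bit_score bit-score threshold (strict)
#' @param min_aligned_columns aligned-position floor (inclusive)
#' @param fold_probability_threshold structure-hit probability
#'   threshold (strict) for all folds except the beta-helix
#' @param beta_helix_probability_threshold relaxed strict threshold
#'   for right-handed beta-helix hits
#' @param max_per_cluster_per_annotation diversity cap
#' @param cdhit_identity,cdhit_coverage,ap_damping recorded clustering
#'   constants of the external adapters
#' @return object of class `curation_config`
#' @export
curation_config <- function(min_length = 200L,
                            min_bit_score = 20,
                            min_aligned_columns = 30L,
                            fold_probability_threshold = 0.5,
                            beta_helix_probability_threshold = 0.2,
                            max_per_cluster_per_annotation = 5L,
                            cdhit_identity = 0.95,
                            cdhit_coverage = 0.80,
                            ap_damping = 0.90) {
  stopifnot(min_length >= 1, min_aligned_columns >= 0,
            fold_probability_threshold >= 0, fold_probability_threshold <= 1,
            beta_helix_probability_threshold >= 0,
            beta_helix_probability_threshold <= 1,
            max_per_cluster_per_annotation >= 1,
            cdhit_identity > 0, cdhit_identity <= 1,
            cdhit_coverage > 0, cdhit_coverage <= 1,
            ap_damping >= 0.5, ap_damping < 1)
  structure(list(min_length = as.integer(min_length),
                 min_bit_score = min_bit_score,
                 min_aligned_columns = as.integer(min_aligned_columns),
                 fold_probability_threshold = fold_probability_threshold,
                 beta_helix_probability_threshold =
                   beta_helix_probability_threshold,
                 max_per_cluster_per_annotation =
                   as.integer(max_per_cluster_per_annotation),
                 cdhit_identity = cdhit_identity,
                 cdhit_coverage = cdhit_coverage,
                 ap_damping = ap_damping),
            class = "curation_config")
}

#' Homology and structure hits, clusters
#'
#' Light records for the outputs of the external search tools.
#' `homology_hit()` is one profile-search alignment of a query
#' protein against a polysaccharide-degrading domain entry;
#' `structure_hit()` is one structural match of a (predicted) query
#' structure against the fold database, carrying the matched fold and
#' the probability that the match is a true positive; `protein_cluster()`
#' is one sequence cluster with its representative.
#'
#' @param query_id query protein id
#' @param target_entry matched domain-database entry name
#' @param bit_score alignment bit score (finite)
#' @param aligned_columns number of aligned positions (>= 0)
#' @param query_start,query_end 0-based half-open match interval on
#'   the query
#' @return a `homology_hit` / `structure_hit` / `protein_cluster`
#' @export
homology_hit <- function(query_id, target_entry, bit_score,
                         aligned_columns, query_start = NA_integer_,
                         query_end = NA_integer_) {
  if (!is.finite(bit_score)) stop("bit_score must be finite")
  if (aligned_columns < 0) stop("aligned_columns must be >= 0")
  structure(list(query_id = query_id, target_entry = target_entry,
                 bit_score = bit_score,
                 aligned_columns = as.integer(aligned_columns),
                 query_start = as.integer(query_start),
                 query_end = as.integer(query_end)),
            class = "homology_hit")
}

#' @rdname homology_hit
#' @param target_fold fold name from [curation_folds()]
#' @param probability true-positive-match probability in \[0, 1\]
#' @export
structure_hit <- function(query_id, target_fold, probability,
                          query_start = NA_integer_,
                          query_end = NA_integer_) {
  if (!target_fold %in% curation_folds() || target_fold == "NONE")
    stop("unknown fold '", target_fold, "' for structure hit on '",
         query_id, "'")
  if (!is.numeric(probability) || is.na(probability) ||
      probability < 0 || probability > 1)
    stop("structure-hit probability must be in [0, 1] (query '",
         query_id, "', got ", probability, ")")
  structure(list(query_id = query_id, target_fold = target_fold,
                 probability = probability,
                 query_start = as.integer(query_start),
                 query_end = as.integer(query_end)),
            class = "structure_hit")
}

#' @rdname homology_hit
#' @param cluster_id cluster identifier
#' @param member_ids non-empty character vector of member record ids
#' @param representative_id one of `member_ids`
#' @export
protein_cluster <- function(cluster_id, member_ids, representative_id) {
  if (length(member_ids) == 0L) stop("empty cluster '", cluster_id, "'")
  if (!representative_id %in% member_ids)
    stop("representative '", representative_id,
         "' is not a member of cluster '", cluster_id, "'")
  structure(list(cluster_id = cluster_id,
                 member_ids = as.character(member_ids),
                 representative_id = representative_id),
            class = "protein_cluster")
}

#' Length filter
#'
#' Discards every sequence under `min_length` residues; order of the
#' survivors is preserved.
#'
#' @param records list of [protein_record()]
#' @param min_length inclusive minimum length (default from
#'   [curation_config()]: 200)
#' @return the kept records
#' @export
filter_by_length <- function(records, min_length = 200L) {
  stopifnot(min_length >= 1)
  keep <- vapply(records, record_length, integer(1)) >= min_length
  records[keep]
}

#' Hit-calling rules
#'
#' `call_homology_hit()`: a profile-search hit is positive iff its
#' bit score is strictly above `min_bit_score` and it spans at least
#' `min_aligned_columns` aligned positions.
#' `call_structure_hit()`: a structural hit is positive iff its
#' probability is strictly above the fold threshold — 0.2 for the
#' right-handed beta-helix, 0.5 for every other fold. Both rules are
#' monotone in their score arguments.
#'
#' @param hit a [homology_hit()] or [structure_hit()]
#' @param cfg a [curation_config()]
#' @return logical: is the hit positive
#' @export
call_homology_hit <- function(hit, cfg = curation_config()) {
  stopifnot(inherits(hit, "homology_hit"))
  hit$bit_score > cfg$min_bit_score &&
    hit$aligned_columns >= cfg$min_aligned_columns
}

#' @rdname call_homology_hit
#' @export
call_structure_hit <- function(hit, cfg = curation_config()) {
  stopifnot(inherits(hit, "structure_hit"))
  thr <- if (hit$target_fold == "BETA_HELIX")
    cfg$beta_helix_probability_threshold else cfg$fold_probability_threshold
  hit$probability > thr
}

#' Cluster representative selection
#'
#' The representative of a cluster is its longest member; ties are
#' broken by lexicographically smallest id.
#'
#' @param members non-empty list of [protein_record()]
#' @return the representative [protein_record()]
#' @export
select_representative <- function(members) {
  if (length(members) == 0L) stop("cannot pick a representative of an empty cluster")
  lens <- vapply(members, record_length, integer(1))
  ids <- vapply(members, `[[`, character(1), "id")
  ord <- order(-lens, ids)
  members[[ord[1]]]
}

#' Diversity cap per cluster and annotation
#'
#' For every (cluster, annotation) pair at most
#' `cfg$max_per_cluster_per_annotation` records are kept (default 5),
#' preferring the longest (id tie-break). Records whose annotation is
#' not on the allowed list are excluded; a record with no cluster
#' assignment is an error.
#'
#' @param clusters list of [protein_cluster()] covering all records
#' @param records list of [protein_record()]
#' @param allowed_annotations character vector of annotations
#'   consistent with depolymerase activity
#' @param cfg a [curation_config()]
#' @return the selected records, in input order
#' @export
cap_by_annotation <- function(clusters, records, allowed_annotations,
                              cfg = curation_config()) {
  if (length(allowed_annotations) == 0L)
    stop("allowed_annotations must be non-empty")
  ids <- check_records(records)
  cluster_of <- character(0)
  for (cl in clusters)
    cluster_of[cl$member_ids] <- cl$cluster_id
  unassigned <- ids[!ids %in% names(cluster_of)]
  if (length(unassigned))
    stop("record(s) with no cluster assignment: ",
         paste(unassigned, collapse = ", "))
  ann <- vapply(records, `[[`, character(1), "annotation")
  lens <- vapply(records, record_length, integer(1))
  allowed <- !is.na(ann) & ann %in% allowed_annotations
  keep <- logical(length(records))
  idx_allowed <- which(allowed)
  if (length(idx_allowed)) {
    key <- paste(cluster_of[ids[idx_allowed]], ann[idx_allowed], sep = "\r")
    for (k in unique(key)) {
      grp <- idx_allowed[key == k]
      ord <- grp[order(-lens[grp], ids[grp])]
      keep[utils::head(ord, cfg$max_per_cluster_per_annotation)] <- TRUE
    }
  }
  records[keep]
}

#' Parse CD-HIT .clstr cluster files
#'
#' Standard `.clstr` dialect: blocks opened by `>Cluster k`, member
#' lines of the form `n<TAB>LENaa, >ID... *` where the `*` flags the
#' tool's representative and `...` truncates the id. Malformed lines
#' and blocks without a representative are rejected, never skipped.
#'
#' @param path `.clstr` file path
#' @return list of [protein_cluster()]
#' @export
parse_cdhit_clstr <- function(path) {
  if (!file.exists(path)) stop(".clstr file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  clusters <- list()
  cur_id <- NULL; cur_members <- character(0); cur_rep <- NULL
  flush <- function() {
    if (is.null(cur_id)) return()
    if (is.null(cur_rep))
      stop("cluster '", cur_id, "' has no representative ('*') member")
    clusters[[length(clusters) + 1L]] <<-
      protein_cluster(cur_id, cur_members, cur_rep)
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      cur_id <- trimws(sub("^>", "", ln))
      cur_members <- character(0); cur_rep <- NULL
      next
    }
    if (is.null(cur_id))
      stop("member line before any cluster header: '", ln, "'")
    m <- regmatches(ln, regexec("^\\d+\\s+\\d+aa,\\s*>(.*?)(\\.\\.\\.)?\\s*(\\*|at\\s.*|$)",
                                ln, perl = TRUE))[[1]]
    if (length(m) == 0L || !nzchar(m[2]))
      stop("malformed .clstr member line: '", ln, "'")
    id <- m[2]
    cur_members <- c(cur_members, id)
    if (grepl("\\*\\s*$", ln)) cur_rep <- id
  }
  flush()
  clusters
}

#' Parse structural-search hit tables
#'
#' Tabular dialect `query<TAB>target<TAB>prob<TAB>qstart<TAB>qend`
#' (whitespace- or tab-separated, no header). Target names are mapped
#' to fold labels through `fold_map` (a named character vector or the
#' contents of a fold-map YAML, `target_name: fold_label`); a target
#' with no map entry, or a probability outside \[0, 1\], is an error.
#'
#' @param path hit table path
#' @param fold_map named character vector mapping target names to
#'   [curation_folds()] entries, or a YAML file path
#' @return list of [structure_hit()]
#' @export
parse_structure_hits <- function(path, fold_map) {
  if (!file.exists(path)) stop("structure-hit file not found: ", path)
  if (is.character(fold_map) && length(fold_map) == 1L &&
      is.null(names(fold_map)) && file.exists(fold_map))
    fold_map <- unlist(yaml::read_yaml(fold_map))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 5L)
      stop("malformed structure-hit line (need 5 columns): '", ln, "'")
    p <- suppressWarnings(as.numeric(f[3]))
    if (is.na(p) || p < 0 || p > 1)
      stop("structure-hit probability outside [0, 1]: '", f[3],
           "' (query '", f[1], "')")
    if (!f[2] %in% names(fold_map))
      stop("no fold-map entry for target '", f[2], "'")
    fold <- unname(fold_map[[f[2]]])
    structure_hit(f[1], fold, p, as.integer(f[4]), as.integer(f[5]))
  })
}

#' @rdname parse_structure_hits
#' @return `parse_homology_hits()`: list of [homology_hit()] from a
#'   `query<TAB>entry<TAB>bit_score<TAB>aligned_cols<TAB>qstart<TAB>qend`
#'   table
#' @export
parse_homology_hits <- function(path) {
  if (!file.exists(path)) stop("homology-hit file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 6L)
      stop("malformed homology-hit line (need 6 columns): '", ln, "'")
    bs <- suppressWarnings(as.numeric(f[3]))
    ac <- suppressWarnings(as.integer(f[4]))
    if (is.na(bs) || is.na(ac))
      stop("malformed homology-hit numbers in line: '", ln, "'")
    homology_hit(f[1], f[2], bs, ac, as.integer(f[5]), as.integer(f[6]))
  })
}

#' Run the full curation funnel
#'
#' Applies the curation decision rules in pipeline order and records
#' the survivor set of every stage: (1) length filter; (2) keep
#' records with at least one positive profile-search hit; (3) keep
#' cluster representatives (longest member) of the sequence clusters;
#' (4) diversity cap per (cluster, annotation); (5) keep records with
#' at least one positive structural hit, which also assigns the
#' record its fold (highest-probability positive hit; ties broken by
#' longest match interval).
#'
#' @param records list of [protein_record()]
#' @param homology_hits list of [homology_hit()]
#' @param structure_hits list of [structure_hit()]
#' @param cdhit_clusters list of [protein_cluster()] — the
#'   fine-grained sequence-identity clusters whose longest member is
#'   kept as representative
#' @param ap_clusters the coarse embedding clusters the diversity cap
#'   operates on: a list of [protein_cluster()] or a named character
#'   vector (cluster id per record id)
#' @param allowed_annotations annotations consistent with
#'   depolymerase activity
#' @param cfg a [curation_config()]
#' @return list with `curated` (records), `folds` (named fold per
#'   curated id), `funnel` (data frame of per-stage counts) and
#'   `survivors` (per-stage id vectors)
#' @export
curate_records <- function(records, homology_hits, structure_hits,
                           cdhit_clusters, ap_clusters,
                           allowed_annotations,
                           cfg = curation_config()) {
  clusters <- cdhit_clusters
  if (!is.list(ap_clusters)) {
    ap_clusters <- lapply(split(names(ap_clusters), ap_clusters),
                          function(ids) protein_cluster(
                            unname(ap_clusters[ids[1]]), ids, ids[1]))
  }
  stages <- list()
  note <- function(stage, recs) stages[[stage]] <<- length(recs)

  s1 <- filter_by_length(records, cfg$min_length)
  note("length_filter", s1)

  pos <- vapply(homology_hits, call_homology_hit, logical(1), cfg = cfg)
  hit_ids <- unique(vapply(homology_hits[pos], `[[`, character(1), "query_id"))
  s2 <- s1[vapply(s1, `[[`, character(1), "id") %in% hit_ids]
  note("homology_hit", s2)

  s2_ids <- vapply(s2, `[[`, character(1), "id")
  by_id <- stats::setNames(s2, s2_ids)
  reps <- character(0)
  for (cl in clusters) {
    members <- by_id[intersect(cl$member_ids, s2_ids)]
    if (length(members))
      reps <- c(reps, select_representative(unname(members))$id)
  }
  s3 <- s2[s2_ids %in% reps]
  note("cluster_representative", s3)

  s4 <- cap_by_annotation(ap_clusters, s3, allowed_annotations, cfg)
  note("annotation_cap", s4)

  pos_struct <- structure_hits[vapply(structure_hits, call_structure_hit,
                                      logical(1), cfg = cfg)]
  folds <- character(0)
  if (length(pos_struct)) {
    qid <- vapply(pos_struct, `[[`, character(1), "query_id")
    for (id in unique(qid)) {
      hits <- pos_struct[qid == id]
      p <- vapply(hits, `[[`, numeric(1), "probability")
      span <- vapply(hits, function(h) {
        s <- h$query_end - h$query_start
        if (is.na(s)) 0L else s
      }, integer(1))
      best <- hits[[order(-p, -span)[1]]]
      folds[id] <- best$target_fold
    }
  }
  s5 <- s4[vapply(s4, `[[`, character(1), "id") %in% names(folds)]
  note("structure_confirmed", s5)

  funnel <- data.frame(stage = c("input", names(stages)),
                       n = c(length(records), unlist(stages, use.names = FALSE)),
                       stringsAsFactors = FALSE)
  survivors <- lapply(list(input = records, length_filter = s1,
                           homology_hit = s2, cluster_representative = s3,
                           annotation_cap = s4, structure_confirmed = s5),
                      function(rs) vapply(rs, `[[`, character(1), "id"))
  list(curated = s5,
       folds = folds[vapply(s5, `[[`, character(1), "id")],
       funnel = funnel,
       survivors = survivors)
}
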