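#' Per-class descriptor profiles (class means)
#'
#' Computes the arithmetic mean of every descriptor column over the member
#' sequences of each annotated class, including the `"non-enzyme"` pool.
#' These class means are the `<d>` half of the multi-task featurization;
#' the other half is the per-sequence deviation `D = d - <d>`.
#'
#' @param desc Descriptor `data.frame` from [descriptor_table()].
#' @param annotations `data.frame` with `sequence_id`, `class_id`.
#' @return `data.frame` with columns `class_id`, `count`, and one mean
#'   column per descriptor, sorted by `class_id`.
#' @export
compute_class_profiles <- function(desc, annotations) {
  stopifnot(is.data.frame(desc), "sequence_id" %in% names(desc))
  missing <- setdiff(annotations$sequence_id, desc$sequence_id)
  if (length(missing) > 0L) {
    stop("annotated class member(s) absent from descriptor table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  merged <- merge(annotations, desc, by = "sequence_id")
  feats <- setdiff(names(desc), "sequence_id")
  split_rows <- split(merged[, feats, drop = FALSE], merged$class_id)
  prof <- do.call(rbind, lapply(names(split_rows), function(cl) {
    block <- split_rows[[cl]]
    cbind(data.frame(class_id = cl, count = nrow(block),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(block))))
  }))
  prof <- prof[order(prof$class_id), , drop = FALSE]
  rownames(prof) <- NULL
  prof
}

#' Deviation of a sequence's descriptors from a class profile
#'
#' @param x Named numeric vector of descriptor values, or a one-row
#'   descriptor `data.frame`.
#' @param profile A one-row profile (from [compute_class_profiles()]).
#' @return Named numeric vector `x - mean`, over the descriptor names shared
#'   with the profile; an error if a profile descriptor is missing in `x`.
#' @export
deviation <- function(x, profile) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- unlist(x[, setdiff(names(x), "sequence_id"), drop = FALSE])
  }
  stopifnot(is.data.frame(profile), nrow(profile) == 1L)
  feats <- setdiff(names(profile), c("class_id", "count"))
  absent <- setdiff(feats, names(x))
  if (length(absent) > 0L) {
    stop("descriptor(s) missing from x: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  vals <- unlist(profile[, feats, drop = FALSE])
  stats::setNames(as.numeric(x[feats]) - as.numeric(vals), feats)
}

#' Build (sequence, candidate class) pair records
#'
#' The multi-task table has one row per (sequence, candidate class) pair:
#' the candidate class's descriptor means (`<d>` columns, named
#' `<feature>_mean`), the sequence's deviations from them (`D<feature>`),
#' and the label `+1` (enzyme of that class) or `-1` (not). Each enzyme
#' contributes one positive row against its annotated class. Each
#' non-enzyme contributes negative rows against enzyme classes chosen by
#' `negative_policy`:
#' \describe{
#'   \item{`"random-class"`}{one row against a uniformly random enzyme
#'     subclass (seeded); total rows = number of sequences.}
#'   \item{`"all-classes"`}{one row against every enzyme subclass.}
#'   \item{`"cross-class"`}{as `"all-classes"`, and additionally each
#'     enzyme yields a negative record against every subclass other than
#'     its own (one-vs-rest expansion). Needed when a nonlinear model is
#'     to be used for subclass assignment via [predict_subclass()]: without
#'     enzyme-versus-wrong-class examples no trained pair scorer can
#'     separate candidate classes.}
#' }
#'
#' @param desc Descriptor `data.frame`.
#' @param annotations `data.frame` with `sequence_id`, `class_id`.
#' @param profiles From [compute_class_profiles()].
#' @param features Descriptor columns to featurize; default `c("Tr3", "Tr5")`,
#'   the published model's inputs.
#' @param negative_policy `"random-class"` (default) or `"all-classes"`.
#' @param seed Integer seed for the random negative pairing; `NULL` leaves
#'   the RNG state alone.
#' @return `data.frame` with columns `sequence_id`, `class_id`,
#'   `<feature>_mean` and `D<feature>` for each feature, and `label`.
#' @export
make_pairs <- function(desc, annotations, profiles,
                       features = c("Tr3", "Tr5"),
                       negative_policy = "random-class", seed = NULL) {
  if (!negative_policy %in% c("random-class", "all-classes",
                              "cross-class")) {
    stop("unknown negative_policy: ", negative_policy, call. = FALSE)
  }
  stopifnot(all(features %in% names(desc)), all(features %in% names(profiles)))
  enzyme_classes <- sort(setdiff(profiles$class_id, "non-enzyme"))
  if (length(enzyme_classes) == 0L) {
    stop("no enzyme class profiles", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  merged <- merge(annotations, desc, by = "sequence_id")
  is_enzyme <- merged$class_id != "non-enzyme"
  cand <- lapply(seq_len(nrow(merged)), function(i) {
    if (is_enzyme[i]) {
      if (negative_policy == "cross-class") {
        # own class first, then the one-vs-rest negatives
        c(merged$class_id[i],
          setdiff(enzyme_classes, merged$class_id[i]))
      } else {
        merged$class_id[i]
      }
    } else if (negative_policy == "random-class") {
      if (length(enzyme_classes) == 1L) enzyme_classes
      else sample(enzyme_classes, 1L)
    } else {
      enzyme_classes
    }
  })
  n_per <- lengths(cand)
  rows <- merged[rep(seq_len(nrow(merged)), n_per), , drop = FALSE]
  rows$candidate <- unlist(cand)
  pidx <- match(rows$candidate, profiles$class_id)
  if (anyNA(pidx)) {
    stop("no profile for class(es): ",
         paste(unique(rows$candidate[is.na(pidx)]), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(sequence_id = rows$sequence_id,
                    class_id = rows$candidate,
                    stringsAsFactors = FALSE)
  for (f in features) {
    out[[paste0(f, "_mean")]] <- profiles[[f]][pidx]
    out[[paste0("D", f)]] <- rows[[f]] - profiles[[f]][pidx]
  }
  out$label <- ifelse(rep(is_enzyme, n_per) & rows$candidate == rows$class_id,
                      1L, -1L)
  rownames(out) <- NULL
  out
}

#' Predict the EC subclass of a sequence (or call it a non-enzyme)
#'
#' Scores the sequence against every enzyme-class profile by forming the
#' pair features (class means + deviations) and applying the model. The
#' highest-scoring class is returned if its score classifies positive at
#' the threshold; otherwise `"non-enzyme"`. Score ties are broken by the
#' lexicographically smallest EC string.
#'
#' @param x Named numeric descriptor vector or one-row descriptor
#'   `data.frame` for a single sequence.
#' @param profiles From [compute_class_profiles()].
#' @param model A `linear_model` (default: the published equation,
#'   [ec_published_model()]) or `mlp_model`.
#' @param threshold Decision threshold on the score (default 0; exact ties
#'   classify negative).
#' @param features Descriptor names used by the model.
#' @return List with `class_id` (an EC string or `"non-enzyme"`), `score`
#'   (the winning score), and `scores` (named vector over all classes).
#' @export
predict_subclass <- function(x, profiles, model = ec_published_model(),
                             threshold = 0, features = c("Tr3", "Tr5")) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- unlist(x[, setdiff(names(x), "sequence_id"), drop = FALSE])
  }
  enzyme <- profiles[profiles$class_id != "non-enzyme", , drop = FALSE]
  if (nrow(enzyme) == 0L) stop("no enzyme class profiles", call. = FALSE)
  feat_rows <- do.call(rbind, lapply(seq_len(nrow(enzyme)), function(i) {
    row <- stats::setNames(
      as.list(c(unlist(enzyme[i, features, drop = FALSE]),
                as.numeric(x[features]) -
                  as.numeric(enzyme[i, features, drop = FALSE]))),
      c(paste0(features, "_mean"), paste0("D", features)))
    as.data.frame(row)
  }))
  scores <- stats::setNames(score_pairs(model, feat_rows), enzyme$class_id)
  ord <- order(-scores, names(scores))
  best <- ord[1]
  cls <- if (classify(scores[best], threshold) > 0) {
    names(scores)[best]
  } else "non-enzyme"
  list(class_id = cls, score = unname(scores[best]), scores = scores)
}

#' Write class profiles to TSV
#'
#' @param profiles From [compute_class_profiles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read class profiles from TSV
#'
#' @param path Path written by [write_profiles()].
#' @return Profile `data.frame`.
#' @export
read_profiles <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write pair records to TSV
#'
#' @param pairs From [make_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read pair records from TSV
#'
#' @param path Path written by [write_pairs()].
#' @return Pair `data.frame`.
#' @export
read_pairs <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
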