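#' Declare a deterministic linkage pass
#'
#' A pass is an ordered set of key names that must all agree exactly
#' (and all be non-missing) for two episodes to match in that pass.
#' Passes are applied in declared order; merging is transitive, so the
#' final person assignment is an order-independent partition.
#'
#' @param keys character vector of key names; valid keys are
#'   `"sex"`, `"dob"`, `"postcode"`, `"medicare"`, `"country"`.
#' @return an object of class `linkage_pass`.
#' @export
linkage_pass <- function(keys) {
  keys <- as.character(keys)
  valid <- c("sex", "dob", "postcode", "medicare", "country")
  if (length(keys) == 0) stop("a linkage pass needs at least one key",
                              call. = FALSE)
  unknown <- setdiff(keys, valid)
  if (length(unknown)) {
    stop("unknown linkage key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  structure(list(keys = keys), class = "linkage_pass")
}

#' Default stepwise linkage passes
#'
#' Three passes emulating the matching core of a stepwise deterministic
#' production linkage: (1) sex + date of birth + Medicare number,
#' (2) sex + date of birth + postcode + country of birth, (3) Medicare
#' number alone (format-validated during key standardisation).  This is
#' a documented configuration default, not a claim about any production
#' system's actual step list.
#'
#' @return list of [linkage_pass()] objects.
#' @export
default_linkage_passes <- function() {
  list(linkage_pass(c("sex", "dob", "medicare")),
       linkage_pass(c("sex", "dob", "postcode", "country")),
       linkage_pass("medicare"))
}

#' Standardise linkage keys
#'
#' Trims and case-folds string keys, parses dates of birth (impossible
#' calendar dates are flagged and treated as missing, never fatal),
#' normalises sex to F/M, keeps only well-formed four-digit postcodes
#' and ten-digit Medicare surrogates, and unifies null markers to `NA`.
#' Missing keys never match anything in [link_records()].
#'
#' @param episodes episode table with raw `key_*` columns.
#' @return the episode table with standardised `key_*` columns plus a
#'   logical `key_dob_valid` flag.
#' @export
standardise_keys <- function(episodes) {
  blank_na <- function(x) {
    x <- trimws(x)
    x[!is.na(x) & (x == "" | toupper(x) %in% c("NA", "NULL", "UNKNOWN"))] <- NA
    x
  }
  sex <- toupper(blank_na(episodes$key_sex))
  sex[!sex %in% c("F", "M")] <- NA

  dob_chr <- blank_na(episodes$key_dob)
  dob <- as.Date(dob_chr, format = "%Y-%m-%d")
  # reject real-looking but impossible dates (e.g. 1930-02-30 rolls over
  # or NAs depending on platform; re-format to verify round-trip)
  ok <- !is.na(dob) & format(dob, "%Y-%m-%d") == dob_chr
  dob[!ok] <- NA
  valid_dob <- ok
  valid_dob[is.na(dob_chr)] <- NA

  postcode <- blank_na(episodes$key_postcode)
  postcode[!is.na(postcode) & !grepl("^[0-9]{4}$", postcode)] <- NA

  medicare <- gsub("[ -]", "", blank_na(episodes$key_medicare))
  medicare[!is.na(medicare) & !grepl("^[0-9]{10}$", medicare)] <- NA

  country <- toupper(gsub("[[:space:]]+", " ", blank_na(episodes$key_country)))

  episodes$key_sex <- sex
  episodes$key_dob <- dob
  episodes$key_postcode <- postcode
  episodes$key_medicare <- medicare
  episodes$key_country <- country
  episodes$key_dob_valid <- valid_dob
  episodes
}

#' Collapse episodes to persons by stepwise deterministic linkage
#'
#' Within each pass, episodes agreeing exactly on every pass key (all
#' keys non-missing) are merged; merges are transitive across passes
#' (A-B and B-C imply one person), yielding an equivalence partition of
#' episodes.  Person identifiers are assigned canonically from the
#' smallest episode id in each cluster, so the result is independent of
#' input order.
#'
#' @param episodes episode table, keys already standardised by
#'   [standardise_keys()].
#' @param passes non-empty list of [linkage_pass()] objects.
#' @return a `linkage_result`: tibble (`episode_id`,
#'   `person_id`, `pass` = pass at which the episode first merged with
#'   another, NA for singletons), with a `merges` attribute counting
#'   cluster merges per pass.
#' @export
link_records <- function(episodes, passes) {
  if (length(passes) == 0) stop("empty linkage pass list", call. = FALSE)
  passes <- lapply(passes, function(p) {
    if (inherits(p, "linkage_pass")) p else linkage_pass(p)
  })
  m <- nrow(episodes)
  ord <- order(episodes$episode_id)
  eps <- episodes[ord, , drop = FALSE]

  parent <- seq_len(m)
  # union-find with path halving
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  first_pass <- rep(NA_integer_, m)
  merges <- integer(length(passes))

  for (p in seq_along(passes)) {
    keys <- paste0("key_", passes[[p]]$keys)
    missing_cols <- setdiff(keys, names(eps))
    if (length(missing_cols)) {
      stop("pass ", p, " references unknown key column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    kv <- lapply(keys, function(k) eps[[k]])
    complete <- !Reduce(`|`, lapply(kv, is.na))
    if (!any(complete)) next
    sig <- do.call(paste, c(kv, sep = "\r"))
    idx <- which(complete)
    grp <- split(idx, sig[idx])
    for (g in grp) {
      if (length(g) < 2) next
      r1 <- find(g[1])
      for (j in g[-1]) {
        r2 <- find(j)
        if (r1 != r2) {
          parent[max(r1, r2)] <- min(r1, r2)
          merges[p] <- merges[p] + 1L
          r1 <- min(r1, r2)
        }
      }
      first_pass[g][is.na(first_pass[g])] <- p
    }
  }

  root <- vapply(seq_len(m), find, 0L)
  # canonical ids: clusters ordered by smallest member episode id
  person_id <- sprintf("L%06d", match(root, sort(unique(root))))
  out <- tibble::tibble(episode_id = eps$episode_id,
                        person_id = person_id,
                        pass = first_pass)
  attr(out, "merges") <- tibble::tibble(pass = seq_along(passes),
                                        n_merges = merges)
  class(out) <- c("linkage_result", class(out))
  out
}

#' Score linkage quality against ground truth
#'
#' False positive rate: episode pairs assigned to one person whose true
#' persons differ, over all assigned (within-cluster) pairs.  False
#' negative rate: inter-hospital transfer sender/receiver pairs of one
#' true person left in different clusters, over all same-person transfer
#' pairs.  A zero denominator yields `NA`, not 0.
#'
#' @param result a [link_records()] result covering all episodes in
#'   `truth`.
#' @param truth a `cohort_truth` (needs `$episodes` and `$transfers`).
#' @return list with `false_positive_rate`, `false_negative_rate`,
#'   `n_matched_pairs`, `n_transfer_pairs`.
#' @export
linkage_quality <- function(result, truth) {
  key <- dplyr::inner_join(result, truth$episodes[c("episode_id",
                                                    "true_person_id")],
                           by = "episode_id")
  if (nrow(key) < nrow(truth$episodes)) {
    stop("linkage result does not cover all episodes in truth",
         call. = FALSE)
  }
  pairs2 <- function(n) n * (n - 1) / 2
  cl <- table(key$person_id)
  total_pairs <- sum(pairs2(as.numeric(cl)))
  both <- table(paste(key$person_id, key$true_person_id, sep = "\r"))
  same_pairs <- sum(pairs2(as.numeric(both)))
  fp <- if (total_pairs > 0) (total_pairs - same_pairs) / total_pairs else NA_real_

  tr <- truth$transfers
  fn <- NA_real_
  n_tr <- 0L
  if (!is.null(tr) && nrow(tr) > 0) {
    assigned <- stats::setNames(result$person_id, result$episode_id)
    keep <- tr$sender_episode_id %in% names(assigned) &
      tr$receiver_episode_id %in% names(assigned)
    tr <- tr[keep, , drop = FALSE]
    n_tr <- nrow(tr)
    if (n_tr > 0) {
      fn <- mean(assigned[tr$sender_episode_id] !=
                   assigned[tr$receiver_episode_id])
    }
  }
  list(false_positive_rate = fp, false_negative_rate = fn,
       n_matched_pairs = total_pairs, n_transfer_pairs = n_tr)
}
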