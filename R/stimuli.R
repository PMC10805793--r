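# Constrained letter-string stimulus generation.
#
# Two stimulus sets: a vowel-detection set (experiment 1: strings with
# exactly one vowel vs. all-consonant strings) and a pronounceability set
# (experiment 2: pronounceable vs. unpronounceable strings, both with
# exactly one vowel). All strings are 5 lowercase letters, contain no 'y',
# and have at least four unique letters.

# Orthographic legality whitelist. Pronounceability is defined here as a
# deterministic template rule: a string is pronounceable iff it is
# onset + vowel + coda with the onset and coda drawn from these lists of
# legal English word-initial and word-final consonant clusters.
LEGAL_ONSETS <- c(
  "bl", "br", "ch", "cl", "cr", "dr", "fl", "fr", "gl", "gr",
  "pl", "pr", "sc", "sh", "sk", "sl", "sm", "sn", "sp", "st",
  "sw", "th", "tr", "tw", "wh", "wr"
)
LEGAL_CODAS <- c(
  "ch", "ck", "ct", "ft", "ld", "lf", "lk", "lm", "lp", "lt",
  "mp", "nd", "nk", "nt", "pt", "rd", "rk", "rl", "rm", "rn",
  "rp", "rt", "sh", "sk", "sp", "st", "th"
)

#' Test whether letter strings are pronounceable
#'
#' A 5-letter string counts as pronounceable when it decomposes as a legal
#' two-consonant onset, a single vowel in the middle position, and a legal
#' two-consonant coda (e.g. "crult" = "cr" + "u" + "lt"). Any other
#' arrangement (e.g. "crtul") is unpronounceable. This is a deterministic
#' whitelist rule standing in for corpus-based bigram/trigram legality.
#'
#' @param text character vector of lowercase 5-letter strings.
#' @return logical vector.
#' @export
#' @examples
#' is_pronounceable(c("crult", "crtul"))
is_pronounceable <- function(text) {
  ok <- nchar(text) == 5L & !grepl("[^a-z]", text)
  mid <- substr(text, 3, 3)
  one_vowel <- vapply(text, function(s) {
    sum(strsplit(s, "")[[1]] %in% VOWELS) == 1L
  }, logical(1), USE.NAMES = FALSE)
  ok & one_vowel & mid %in% VOWELS &
    substr(text, 1, 2) %in% LEGAL_ONSETS &
    substr(text, 4, 5) %in% LEGAL_CODAS
}

n_unique_letters <- function(text) {
  vapply(strsplit(text, ""), function(ch) length(unique(ch)), integer(1))
}

count_vowels <- function(text) {
  vapply(strsplit(text, ""), function(ch) sum(ch %in% VOWELS), integer(1))
}

# Rejection-sample `n` unique strings from `propose(k)` subject to
# `accept(text)`; errors out if the acceptance rate suggests the constraint
# set cannot supply n distinct strings.
sample_constrained <- function(n, propose, accept, what) {
  out <- character(0)
  stall <- 0L
  while (length(out) < n) {
    cand <- unique(propose(max(1000L, 4L * (n - length(out)))))
    cand <- setdiff(cand[accept(cand)], out)
    if (length(cand) == 0L) {
      stall <- stall + 1L
      if (stall > 50L) {
        stop("cannot generate ", n, " distinct ", what,
             " strings under the constraints", call. = FALSE)
      }
    } else {
      stall <- 0L
    }
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

paste_rows <- function(m) do.call(paste0, as.data.frame(m))

#' Generate the vowel-detection stimulus set
#'
#' Signal-present strings contain exactly one vowel (a, e, i, o, u) and four
#' consonants; signal-absent strings are five consonants including at least
#' one of the visually vowel-like consonants q, j, c, n, s. No string
#' contains 'y', all have at least four unique letters, and none is
#' pronounceable under [is_pronounceable()].
#'
#' @param n_per_category number of unique strings per category.
#' @param seed integer seed; output is deterministic given the seed.
#' @return a tibble with columns `text`, `category` ("present"/"absent"),
#'   `experiment` (= 1).
#' @export
gen_stimuli_exp1 <- function(n_per_category, seed) {
  stopifnot(n_per_category >= 1)
  if (n_per_category > 100000) {
    stop("n_per_category exceeds the satisfiable stimulus count", call. = FALSE)
  }
  set.seed(seed)

  propose_present <- function(k) {
    m <- matrix(sample(CONSONANTS, 4L * k, replace = TRUE), k, 4)
    v <- sample(VOWELS, k, replace = TRUE)
    pos <- sample.int(5L, k, replace = TRUE)
    full <- matrix("", k, 5)
    for (i in seq_len(k)) {
      full[i, ] <- append(m[i, ], v[i], after = pos[i] - 1L)
    }
    paste_rows(full)
  }
  accept_present <- function(s) {
    n_unique_letters(s) >= 4L & !is_pronounceable(s)
  }

  propose_absent <- function(k) {
    m <- matrix(sample(CONSONANTS, 5L * k, replace = TRUE), k, 5)
    paste_rows(m)
  }
  accept_absent <- function(s) {
    has_vowel_like <- grepl(paste0("[", paste(VOWEL_LIKE, collapse = ""), "]"), s)
    n_unique_letters(s) >= 4L & has_vowel_like
  }

  present <- sample_constrained(n_per_category, propose_present,
                                accept_present, "vowel-present")
  absent <- sample_constrained(n_per_category, propose_absent,
                               accept_absent, "vowel-absent")
  tibble::tibble(
    text = c(present, absent),
    category = rep(c("present", "absent"), each = n_per_category),
    experiment = 1L
  )
}

#' Generate the pronounceability stimulus set
#'
#' Pronounceable strings are built from the onset/vowel/coda templates of
#' [is_pronounceable()]; unpronounceable strings contain exactly one vowel
#' and four consonants but violate the template. The two categories are
#' matched on starting letter: for every pronounceable string there is one
#' unpronounceable string with the same first letter.
#'
#' @inheritParams gen_stimuli_exp1
#' @return a tibble with columns `text`, `category` ("present" =
#'   pronounceable, "absent" = unpronounceable), `experiment` (= 2).
#' @export
gen_stimuli_exp2 <- function(n_per_category, seed) {
  stopifnot(n_per_category >= 1)
  max_pron <- length(LEGAL_ONSETS) * length(VOWELS) * length(LEGAL_CODAS)
  if (n_per_category > max_pron) {
    stop("n_per_category exceeds the ", max_pron,
         " distinct pronounceable templates", call. = FALSE)
  }
  set.seed(seed)

  propose_pron <- function(k) {
    paste0(sample(LEGAL_ONSETS, k, replace = TRUE),
           sample(VOWELS, k, replace = TRUE),
           sample(LEGAL_CODAS, k, replace = TRUE))
  }
  accept_pron <- function(s) n_unique_letters(s) >= 4L
  pron <- sample_constrained(n_per_category, propose_pron, accept_pron,
                             "pronounceable")

  # one unpronounceable partner per pronounceable string, same first letter
  unpron <- character(n_per_category)
  taken <- character(0)
  for (i in seq_len(n_per_category)) {
    first <- substr(pron[i], 1, 1)
    repeat {
      rest <- sample(c(sample(VOWELS, 1), sample(CONSONANTS, 3)))
      cand <- paste0(first, paste(rest, collapse = ""))
      if (n_unique_letters(cand) >= 4L && !is_pronounceable(cand) &&
          !(cand %in% taken) && !(cand %in% pron)) {
        unpron[i] <- cand
        taken <- c(taken, cand)
        break
      }
    }
  }

  tibble::tibble(
    text = c(pron, unpron),
    category = rep(c("present", "absent"), each = n_per_category),
    experiment = 2L
  )
}

#' Write a stimulus list to CSV
#'
#' @param stimuli tibble from [gen_stimuli_exp1()] or [gen_stimuli_exp2()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stimuli <- function(stimuli, path) {
  write.csv(stimuli[, c("text", "category")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
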