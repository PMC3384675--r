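## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's state afterwards.  `seed = NULL` uses (and
## advances) the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a uniform random DNA database
#'
#' Draws `n_bases` i.i.d. uniform bases over A/C/G/T.  This synthetic
#' database stands in for a real genomic extract in the benchmark; see the
#' methods vignette for what it does and does not emulate.
#'
#' @param n_bases Database length in bases.
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @return A single DNA string.
#' @examples
#' random_database(20, seed = 1)
#' @export
random_database <- function(n_bases, seed = NULL) {
  n_bases <- as.numeric(n_bases)
  if (length(n_bases) != 1L || is.na(n_bases) || n_bases < 1) {
    stop("`n_bases` must be a positive integer", call. = FALSE)
  }
  with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE),
          collapse = ""))
}

#' Extract random query sequences from a database
#'
#' Draws query lengths uniformly on `[min_len, max_len]` and start
#' positions uniformly over the valid range, recording the true (0-based)
#' start as ground truth.  With `within` set to a block size (typically the
#' scene capacity), each query is instead drawn wholly inside one
#' `within`-sized block of the database, so that under a non-overlapping
#' tiling every query is contained in exactly one scene — the layout of
#' the benchmark, where each query has one positive scene and
#' `n_scenes - 1` negative scenes.
#'
#' @param db A single DNA string.
#' @param n_queries Number of queries to extract (default 303).
#' @param min_len,max_len Query length bounds in bases (defaults 50 and
#'   4,500).
#' @param within Optional block size in bases for within-block extraction.
#' @param seed Optional integer seed.
#' @return A data frame of class `query_set`: columns `id`, `sequence`,
#'   `true_start` (0-based), `length`, `noise_level` (0 for extracted
#'   queries).
#' @export
extract_queries <- function(db, n_queries = 303L, min_len = 50L,
                            max_len = 4500L, within = NULL, seed = NULL) {
  n <- nchar(db)
  if (min_len < 1L || max_len < min_len) {
    stop("need 1 <= min_len <= max_len", call. = FALSE)
  }
  if (max_len > n) stop("`max_len` exceeds the database length", call. = FALSE)
  if (!is.null(within)) {
    if (within < max_len) {
      stop("`within` block size must be >= max_len", call. = FALSE)
    }
    if (within > n) stop("`within` exceeds the database length", call. = FALSE)
  }
  if (n_queries <= 0L) {
    out <- data.frame(id = character(), sequence = character(),
                      true_start = integer(), length = integer(),
                      noise_level = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("query_set", "data.frame")
    return(out)
  }
  with_seed(seed, {
    lens <- min_len + sample.int(max_len - min_len + 1L, n_queries,
                                 replace = TRUE) - 1L
    starts <- vapply(lens, function(L) {
      if (is.null(within)) {
        sample.int(n - L + 1L, 1L) - 1
      } else {
        block <- sample.int(n %/% within, 1L) - 1
        block * within + sample.int(within - L + 1L, 1L) - 1
      }
    }, 0)
    out <- data.frame(
      id = sprintf("q%03d", seq_len(n_queries)),
      sequence = substring(db, starts + 1L, starts + lens),
      true_start = starts, length = lens, noise_level = 0,
      stringsAsFactors = FALSE)
    class(out) <- c("query_set", "data.frame")
    out
  })
}

#' Mutate a sequence by random base substitution
#'
#' Emulates sequence divergence: exactly `round(rate * length)` distinct
#' positions are chosen uniformly without replacement and each chosen base
#' is replaced by one of the other three bases drawn uniformly, so every
#' mutated locus actually changes.  Length is preserved; no indels.
#'
#' @param sequence A single DNA string.
#' @param rate Substitution fraction in \[0, 1\].
#' @param seed Optional integer seed.
#' @param lenient If `TRUE`, substitutes are drawn from all four bases, so
#'   a mutated locus may keep its original base (effective mismatch rate
#'   `0.75 * rate`).  For sensitivity analyses only; default `FALSE`.
#' @return The mutated DNA string.
#' @examples
#' mutate_sequence(strrep("A", 10), rate = 0.3, seed = 1)
#' @export
mutate_sequence <- function(sequence, rate, seed = NULL, lenient = FALSE) {
  if (rate < 0 || rate > 1) stop("`rate` must lie in [0, 1]", call. = FALSE)
  n <- nchar(sequence)
  k <- round(rate * n)
  if (k == 0L) return(sequence)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    pos <- sample.int(n, k)
    chars[pos] <- if (lenient) {
      sample(bases, k, replace = TRUE)
    } else {
      ## original index shifted by 1..3 (mod 4): uniform over the other three
      bases[(match(chars[pos], bases) - 1L +
               sample.int(3L, k, replace = TRUE)) %% 4L + 1L]
    }
    paste(chars, collapse = "")
  })
}

#' Build the full synthetic benchmark inputs
#'
#' Generates the complete experimental bundle: a uniform random database, a
#' base set of queries extracted from within scene-sized blocks, and one
#' substitution-mutated copy of the query set per nonzero noise level.
#' With the defaults (303 queries, noise levels 0–60% in steps of 10%)
#' this yields 303 x 7 = 2,121 query records over a 1 Mbp database split
#' into 100 scenes of 100 x 100 pixels.
#'
#' @param db_size Database length in bases (default 1e6).
#' @param n_queries Base queries per noise level (default 303).
#' @param noise_levels Substitution fractions; level 0 is the unmutated
#'   set (default `seq(0, 0.6, by = 0.1)`).
#' @param scene_width,scene_height Scene dimensions in pixels.
#' @param min_len,max_len Query length bounds.
#' @param seed Optional integer seed controlling the whole bundle.
#' @param lenient Passed to [mutate_sequence()].
#' @return A list of class `benchmark_bundle`: `db` (DNA string),
#'   `queries` (data frame over all levels; ids suffixed `_n<percent>`),
#'   `scene_width`, `scene_height`, `params`.
#' @export
build_benchmark <- function(db_size = 1e6, n_queries = 303L,
                            noise_levels = seq(0, 0.6, by = 0.1),
                            scene_width = 100L, scene_height = 100L,
                            min_len = 50L, max_len = 4500L,
                            seed = NULL, lenient = FALSE) {
  capacity <- scene_width * scene_height
  with_seed(seed, {
    db <- random_database(db_size)
    base <- extract_queries(db, n_queries = n_queries, min_len = min_len,
                            max_len = max_len, within = capacity)
    per_level <- lapply(noise_levels, function(nl) {
      q <- base
      q$noise_level <- nl
      q$id <- sprintf("%s_n%02d", base$id, round(100 * nl))
      if (nl > 0) {
        q$sequence <- vapply(base$sequence, mutate_sequence, "",
                             rate = nl, lenient = lenient,
                             USE.NAMES = FALSE)
      }
      q
    })
    queries <- do.call(rbind, per_level)
    rownames(queries) <- NULL
    structure(
      list(db = db, queries = queries,
           scene_width = as.integer(scene_width),
           scene_height = as.integer(scene_height),
           params = list(db_size = db_size, n_queries = n_queries,
                         noise_levels = noise_levels, min_len = min_len,
                         max_len = max_len, seed = seed,
                         lenient = lenient)),
      class = "benchmark_bundle")
  })
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat(sprintf(
    "<benchmark_bundle> %s bp database, %d query records (%d per level x %d noise levels)\n",
    format(nchar(x$db), big.mark = ","), nrow(x$queries),
    x$params$n_queries, length(x$params$noise_levels)))
  cat(sprintf("  scenes: %d x %d pixels (%s bases each)\n",
              x$scene_height, x$scene_width,
              format(x$scene_width * x$scene_height, big.mark = ",")))
  invisible(x)
}

#' Write a benchmark bundle to FASTA + ground-truth TSV
#'
#' Serializes the database and queries as FASTA and the ground truth
#' (id, true_start 0-based, length, noise_level) as a TSV sidecar.
#'
#' @param bundle A `benchmark_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_benchmark_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  db_path <- file.path(dir, "database.fasta")
  q_path <- file.path(dir, "queries.fasta")
  t_path <- file.path(dir, "truth.tsv")
  write_fasta(c(database = bundle$db), db_path)
  write_fasta(setNames(bundle$queries$sequence, bundle$queries$id), q_path)
  utils::write.table(
    bundle$queries[, c("id", "true_start", "length", "noise_level")],
    t_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(database = db_path, queries = q_path, truth = t_path))
}
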