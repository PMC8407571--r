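# run expr under a local, restorable RNG when seed is given, so generators
# are pure functions of (params, seed) without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate binary addition sequences
#'
#' Samples pairs of addends uniformly from `[0, 2^(m-1))` and returns their
#' bit sequences together with the exact binary sum. Bits are presented
#' least-significant-bit first, so the carry recursion runs causally from
#' the first timestep and the task is solvable by a forward recurrent
#' network. Capping the addends at `2^(m-1)` guarantees the sum fits in `m`
#' bits with no overflow step.
#'
#' @param n number of samples.
#' @param m sequence length in bits (`m >= 2`). The recurrent experiments
#'   use binary numbers up to `2^50`, i.e. `m = 50`.
#' @param seed optional integer seed; when given the generator is a pure
#'   function of `(n, m, seed)`.
#' @return A list with `a`, `b`, `s`: three `n x m` 0/1 matrices (addend
#'   bits and sum bits, LSB first).
#' @examples
#' d <- gen_binary_addition(3, 8, seed = 1)
#' # check one sample as integers
#' bits_to_int <- function(b) sum(b * 2^(seq_along(b) - 1))
#' bits_to_int(d$a[1, ]) + bits_to_int(d$b[1, ]) == bits_to_int(d$s[1, ])
#' @export
gen_binary_addition <- function(n, m, seed = NULL) {
  stopifnot(n >= 1, m >= 2)
  .with_seed(seed, {
    a <- cbind(matrix(stats::rbinom(n * (m - 1), 1, 0.5), n, m - 1), 0)
    b <- cbind(matrix(stats::rbinom(n * (m - 1), 1, 0.5), n, m - 1), 0)
    s <- matrix(0L, n, m)
    carry <- rep(0L, n)
    for (j in seq_len(m)) {
      tot <- a[, j] + b[, j] + carry
      s[, j] <- tot %% 2L
      carry <- tot %/% 2L
    }
    list(a = a, b = b, s = s)
  })
}

# smooth centre-weighted class template on a side x side grid: a sum of
# Gaussian bumps whose centres cluster near the image centre
.make_templates <- function(n_class = 10, side = 28, bumps = 3) {
  xy <- expand.grid(x = seq_len(side), y = seq_len(side))
  centre <- (side + 1) / 2
  lapply(seq_len(n_class), function(k) {
    img <- rep(0, side * side)
    for (bmp in seq_len(bumps)) {
      cx <- stats::rnorm(1, centre, side / 8)
      cy <- stats::rnorm(1, centre, side / 8)
      w <- stats::runif(1, side / 14, side / 7)
      amp <- stats::runif(1, 0.6, 1)
      img <- img + amp * exp(-((xy$x - cx)^2 + (xy$y - cy)^2) / (2 * w^2))
    }
    img / max(img) * 0.9
  })
}

#' Generate a synthetic image classification set
#'
#' A desk-scale stand-in for MNIST-class data: ten fixed random smooth
#' class templates (sums of Gaussian bumps whose centres cluster near the
#' image centre, so that central pixels carry most of the class
#' information), plus pixelwise Gaussian noise, clipped to `[0, 1]`.
#' Classes are exactly balanced.
#'
#' @param n_per_class images per class.
#' @param noise_sd pixelwise noise standard deviation; the default is
#'   calibrated so that a nearest-template classifier scores well above 90%.
#' @param side image side length in pixels (images are `side x side`).
#' @param templates optional list of 10 template vectors (length `side^2`)
#'   to reuse, e.g. to generate a matched test set.
#' @param seed optional integer seed for reproducibility.
#' @return A list with `images` (`n x side^2` matrix in `[0, 1]`), `labels`
#'   (integer classes `0..9`), `templates`, `side`, and `noise_sd`.
#' @export
gen_synthetic_images <- function(n_per_class, noise_sd = 0.3, side = 28,
                                 templates = NULL, seed = NULL) {
  stopifnot(n_per_class >= 1, noise_sd >= 0)
  .with_seed(seed, {
    if (is.null(templates)) templates <- .make_templates(10, side)
    stopifnot(length(templates) == 10)
    n <- 10 * n_per_class
    labels <- rep(0:9, each = n_per_class)
    images <- matrix(0, n, side^2)
    for (i in seq_len(n)) {
      img <- templates[[labels[i] + 1]] +
        stats::rnorm(side^2, 0, noise_sd)
      images[i, ] <- pmin(1, pmax(0, img))
    }
    ord <- sample.int(n)
    list(images = images[ord, , drop = FALSE], labels = labels[ord],
         templates = templates, side = side, noise_sd = noise_sd)
  })
}

# letter -> input neuron group map: six letters, five neurons each,
# non-overlapping, thirty input neurons in total
.letter_groups <- function() {
  letters6 <- c("a", "b", "c", "x", "y", "z")
  stats::setNames(lapply(seq_along(letters6),
                         function(i) ((i - 1) * 5 + 1):(i * 5)),
                  letters6)
}

#' Generate a two-word letter stream
#'
#' Concatenates randomly chosen words from the two-word language
#' `a b...b c` and `x y...y z` (each word picked independently with equal
#' probability, middle letter repeated `n_rep` times) and returns the
#' per-timestep drive over 30 input neurons: each letter activates its own
#' non-overlapping group of 5 input neurons.
#'
#' @param n_words number of words to concatenate.
#' @param n_rep repeats of the middle letter in each word.
#' @param seed optional integer seed.
#' @return A list with `letters` (character vector, one letter per
#'   timestep), `letter_index` (integer codes 1..6 in the order
#'   a, b, c, x, y, z), `drive` (`30 x T` 0/1 matrix), `word_id` (1 or 2 per
#'   timestep), `word_start` (logical, `TRUE` at the first letter of each
#'   word), `n_rep`, and `groups` (the letter to neuron map).
#' @export
gen_word_stream <- function(n_words, n_rep, seed = NULL) {
  stopifnot(n_words >= 1, n_rep >= 1)
  .with_seed(seed, {
    groups <- .letter_groups()
    w1 <- c("a", rep("b", n_rep), "c")
    w2 <- c("x", rep("y", n_rep), "z")
    ids <- sample(1:2, n_words, replace = TRUE)
    letters_seq <- unlist(lapply(ids, function(i) if (i == 1) w1 else w2))
    wlen <- n_rep + 2
    word_id <- rep(ids, each = wlen)
    word_start <- rep(c(TRUE, rep(FALSE, wlen - 1)), n_words)
    T_len <- length(letters_seq)
    drive <- matrix(0L, 30, T_len)
    letter_index <- match(letters_seq, names(groups))
    for (t in seq_len(T_len)) {
      drive[groups[[letter_index[t]]], t] <- 1L
    }
    list(letters = letters_seq, letter_index = letter_index, drive = drive,
         word_id = word_id, word_start = word_start, n_rep = n_rep,
         groups = groups)
  })
}

# minimal IDX writer (big-endian), used for round-trip testing
.write_idx <- function(path, data, labels = FALSE) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (labels) {
    writeBin(as.integer(c(2049, length(data))), con, size = 4,
             endian = "big")
    writeBin(as.raw(data), con)
  } else {
    stopifnot(is.array(data), length(dim(data)) == 3)
    writeBin(as.integer(c(2051, dim(data))), con, size = 4, endian = "big")
    writeBin(as.raw(aperm(data, c(3, 2, 1))), con)
  }
  invisible(path)
}

#' Read IDX-format image or label files
#'
#' Optional loader for externally obtained MNIST/Fashion-MNIST files in IDX
#' format (big-endian magic number and dimensions). Never required by any
#' other part of the package: all experiments run on the internal synthetic
#' generators unless a path is given explicitly.
#'
#' @param image_path path to an IDX image file (magic 2051).
#' @param label_path optional path to the matching IDX label file
#'   (magic 2049); when given, image and label counts must agree.
#' @return A list with `images` (`n x (rows*cols)` matrix scaled to
#'   `[0, 1]`), `labels` (integer vector or `NULL`), and `side` dimensions.
#' @export
read_idx <- function(image_path, label_path = NULL) {
  read_header <- function(con, expect_magic, ndim) {
    hdr <- readBin(con, "integer", n = 1 + ndim, size = 4, endian = "big")
    if (length(hdr) < 1 + ndim || hdr[1] != expect_magic) {
      stop("not a valid IDX file: bad or truncated header (magic ",
           if (length(hdr) >= 1) hdr[1] else "missing", ")")
    }
    hdr[-1]
  }
  con <- file(image_path, "rb")
  on.exit(close(con), add = TRUE)
  dims <- read_header(con, 2051, 3)
  n <- dims[1]
  npix <- dims[2] * dims[3]
  raw_px <- readBin(con, "raw", n = n * npix)
  if (length(raw_px) < n * npix) {
    stop("truncated IDX image file: expected ", n * npix, " pixels, got ",
         length(raw_px))
  }
  images <- matrix(as.integer(raw_px), n, npix, byrow = TRUE) / 255
  labels <- NULL
  if (!is.null(label_path)) {
    con2 <- file(label_path, "rb")
    on.exit(close(con2), add = TRUE)
    n_lab <- read_header(con2, 2049, 1)
    if (n_lab != n) {
      stop("image/label count mismatch: ", n, " images vs ", n_lab,
           " labels")
    }
    raw_lab <- readBin(con2, "raw", n = n_lab)
    if (length(raw_lab) < n_lab) stop("truncated IDX label file")
    labels <- as.integer(raw_lab)
  }
  list(images = images, labels = labels, rows = dims[2], cols = dims[3])
}
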