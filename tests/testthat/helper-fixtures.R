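# shared toy fixtures (small rings; built once per test session)

toyBgvParams <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- bgvParams(31, 64, 4, h = 8)
    val
  }
})

toyBgvKeys <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      set.seed(4101)
      val <<- bgvKeyGen(toyBgvParams())
    }
    val
  }
})

toyYasheParams <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- yasheParamsGen(20, 3, 17, 16, omega = 2^16)
    val
  }
})

toyYasheKeys <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      set.seed(4102)
      val <<- yasheKeyGen(toyYasheParams())
    }
    val
  }
})

# O(n^2) schoolbook multiply-then-long-divide oracle over Z (doubles),
# independent of the C++ path
schoolbookRingMul <- function(av, bv, m, q) {
  phi <- cyclotomic(m)
  n <- length(phi) - 1
  av <- c(av, numeric(n - length(av)))
  bv <- c(bv, numeric(n - length(bv)))
  conv <- numeric(2 * n - 1)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) conv[i + j - 1] <- conv[i + j - 1] + av[i] * bv[j]
  }
  r <- conv
  for (k in length(r):length(phi)) {
    c0 <- r[k]
    if (c0 != 0) {
      idx <- (k - length(phi) + 1):k
      r[idx] <- r[idx] - c0 * phi
    }
  }
  r <- r[seq_len(n)] %% q
  ifelse(r > q / 2, r - q, r)
}

bitsOf <- function(x, mu) (x %/% 2^(0:(mu - 1))) %% 2
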