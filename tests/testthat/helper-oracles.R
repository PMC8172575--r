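# Independent oracles used to verify the package's string metrics and
# grouping against first-principles implementations. Nothing here calls
# package internals: distances come from a hand-written dynamic program,
# components from boolean matrix closure.

# indel edit distance (ins/del cost 1, substitution cost 2) by dynamic
# programming over integer-coded characters
dpIndelDist <- function(a, b) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  na <- length(av); nb <- length(bv)
  if (na == 0) return(nb)
  if (nb == 0) return(na)
  prev <- 0:nb
  for (i in 1:na) {
    cur <- numeric(nb + 1)
    cur[1] <- i
    for (j in 1:nb) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + if (av[i] == bv[j]) 0 else 2)
    }
    prev <- cur
  }
  prev[nb + 1]
}

oracleRatio <- function(a, b) {
  tot <- nchar(a) + nchar(b)
  if (tot == 0) return(1)
  1 - dpIndelDist(a, b) / tot
}

oraclePartial <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  ns <- nchar(a); nl <- nchar(b)
  if (ns == nl) return(oracleRatio(a, b))
  if (ns == 0) return(1)
  starts <- seq_len(nl - ns + 1L)
  max(vapply(starts, function(i)
    oracleRatio(a, substr(b, i, i + ns - 1L)), 0))
}

oracleTokens <- function(x) {
  t <- strsplit(trimws(x), "\\s+")[[1]]
  t[nzchar(t)]
}

oracleTokenSort <- function(a, b) {
  oracleRatio(paste(sort(oracleTokens(a), method = "radix"), collapse = " "),
              paste(sort(oracleTokens(b), method = "radix"), collapse = " "))
}

oracleTokenSet <- function(a, b) {
  ta <- unique(oracleTokens(a)); tb <- unique(oracleTokens(b))
  int <- sort(intersect(ta, tb), method = "radix")
  da <- sort(setdiff(ta, tb), method = "radix")
  db <- sort(setdiff(tb, ta), method = "radix")
  t0 <- paste(int, collapse = " ")
  t1 <- paste(c(int, da), collapse = " ")
  t2 <- paste(c(int, db), collapse = " ")
  max(oracleRatio(t0, t1), oracleRatio(t0, t2), oracleRatio(t1, t2))
}

oracleNumeric <- function(a, b) {
  runs <- function(x) regmatches(x, gregexpr("[0-9]+", x))[[1]]
  ra <- runs(a); rb <- runs(b)
  if (!length(ra) && !length(rb)) return(1)
  elems <- unique(c(ra, rb))
  num <- sum(vapply(elems, function(e) min(sum(ra == e), sum(rb == e)), 0))
  den <- sum(vapply(elems, function(e) max(sum(ra == e), sum(rb == e)), 0))
  num / den
}

# connected-component labels of an undirected graph by Floyd-Warshall style
# boolean transitive closure; edges is a 2-column matrix of node indices
bruteClosure <- function(n, edges) {
  adj <- diag(TRUE, n)
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      adj[edges[k, 1], edges[k, 2]] <- TRUE
      adj[edges[k, 2], edges[k, 1]] <- TRUE
    }
  }
  for (k in seq_len(n))
    adj <- adj | (adj[, k] %o% adj[k, ])
  # label each node by its smallest reachable node
  apply(adj, 1, function(row) min(which(row)))
}

# random printable test strings over a small mixed alphabet
randomStrings <- function(n, maxLen = 12,
                          alphabet = c(letters[1:4], "1", "2", " ")) {
  vapply(seq_len(n), function(i) {
    len <- sample(0:maxLen, 1)
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, "")
}

# a small hand-built inventory for IO / identifier / QC tests
makeToyInventory <- function() {
  SenseInventory(data.frame(
    sf = c("O.C.", "OC", "MS", "MS", "PA"),
    lf = c("oral contraceptives", "oral contraceptive",
           "multiple sclerosis", "mitral stenosis", "physician assistant"),
    source = c("ADAM", "Wiki", "ADAM", "Wiki", "Wiki")))
}

# normalize + assign all identifiers, as the pipeline would
prepareInventory <- function(inv) {
  inv <- normalizeInventory(inv)
  inv <- assignRecordIds(inv, force = TRUE)
  inv <- assignStringIds(inv, "short_form")
  assignStringIds(inv, "long_form")
}
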