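# Independent brute-force oracle for the dip statistic, used only at small n.
#
# Applies the definition directly: the dip is the smallest d for which some
# unimodal CDF G stays within sup-distance d of the empirical CDF. For fixed
# d, feasibility is checked by linear programming over the values of G at
# the data points, for every placement of the mode (each gap between
# adjacent distinct values, on a grid of positions, and exactly at each data
# point); d is located by bisection. Slow but assumption-free: convexity /
# concavity, monotonicity, the jump at the mode and the slope ordering
# across the mode are all explicit LP constraints.

# Phase-1 simplex feasibility check with Bland's rule for the system
# {A2 x >= b2, A1 x <= b1, x >= 0}. Dense tableau; fine at oracle sizes.
lp_feasible <- function(A2, b2, A1, b1, eps = 1e-9) {
  A <- rbind(A2, A1)
  dirs <- c(rep(">=", length(b2)), rep("<=", length(b1)))
  rhs <- c(b2, b1)
  m <- nrow(A); nx <- ncol(A)
  slack <- diag(ifelse(dirs == ">=", -1, 1), m)
  Aeq <- cbind(A, slack)
  neg <- rhs < 0
  Aeq[neg, ] <- -Aeq[neg, , drop = FALSE]; rhs[neg] <- -rhs[neg]
  ntot <- ncol(Aeq)
  Aeq <- cbind(Aeq, diag(m))          # artificials
  N <- ncol(Aeq)
  cost <- c(rep(0, ntot), rep(1, m))
  basis <- ntot + seq_len(m)
  Tb <- cbind(Aeq, rhs)
  repeat {
    cb <- cost[basis]
    red <- cost - as.vector(cb %*% Tb[, seq_len(N), drop = FALSE])
    enter <- which(red < -eps)
    if (length(enter) == 0L) break
    j <- min(enter)                   # Bland
    col <- Tb[, j]
    pos <- which(col > eps)
    if (length(pos) == 0L) break      # unbounded; cannot happen here
    ratios <- Tb[pos, N + 1L] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + eps]
    i <- cand[which.min(basis[cand])] # Bland on ties
    Tb[i, ] <- Tb[i, ] / Tb[i, j]
    for (r in seq_len(m)) if (r != i && abs(Tb[r, j]) > 0) {
      Tb[r, ] <- Tb[r, ] - Tb[r, j] * Tb[i, ]
    }
    basis[i] <- j
  }
  sum(cost[basis] * Tb[, N + 1L]) < 1e-7
}

dip_oracle <- function(x, tol = 1e-5) {
  tab <- table(x[is.finite(x)])
  v <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  J <- length(v)
  n <- sum(cnt)
  if (J == 1L) return(0.5 / n)
  C <- cumsum(cnt)
  lo <- function(d) C / n - d
  hi <- function(d) c(0, C[-J]) / n + d

  # Feasibility LP: variables are G at the data points plus the mode values
  # (w_minus = G(mode-), w = G(mode)). All constraints are linear for a
  # fixed mode position m.
  feasible_split <- function(d, s, m) {
    # mode in the open gap (v_s, v_{s+1}); s in 0..J
    L <- lo(d); H <- hi(d)
    nv <- s + 2L + (J - s)  # y_1..y_s, w_minus, w, z_{s+1}..z_J
    iy <- seq_len(s)
    iwm <- s + 1L
    iw <- s + 2L
    iz <- if (s < J) (s + 2L + seq_len(J - s)) else integer(0)
    A <- NULL; b <- NULL; A1 <- NULL; b1 <- NULL
    # rows: a %*% x >= bb; boot::simplex needs non-negative rhs, so rows
    # with bb < 0 are stored negated as <= constraints
    add <- function(a, bb) {
      if (bb >= 0) { A <<- rbind(A, a); b <<- c(b, bb) }
      else { A1 <<- rbind(A1, -a); b1 <<- c(b1, -bb) }
    }
    row <- function() numeric(nv)
    # bands
    for (j in seq_len(s)) {
      a <- row(); a[iy[j]] <- 1; add(a, max(L[j], 0))
      a <- row(); a[iy[j]] <- -1; add(a, -H[j])
    }
    cs <- if (s == 0) 0 else C[s] / n
    a <- row(); a[iwm] <- 1; add(a, cs - d)
    a <- row(); a[iwm] <- -1; add(a, -min(cs + d, 1))
    a <- row(); a[iw] <- 1; add(a, cs - d)
    a <- row(); a[iw] <- -1; add(a, -min(cs + d, 1))
    a <- row(); a[iw] <- 1; a[iwm] <- -1; add(a, 0)  # w >= w_minus
    for (k in seq_len(J - s)) {
      j <- s + k
      a <- row(); a[iz[k]] <- 1; add(a, L[j])
      a <- row(); a[iz[k]] <- -1; add(a, -min(H[j], 1))
    }
    # monotonicity and convexity of (v_1..v_s, m) with values (y, w_minus)
    pts_x <- c(v[seq_len(s)], m)
    pts_i <- c(iy, iwm)
    np <- length(pts_x)
    for (j in seq_len(np - 1)) {  # nondecreasing
      a <- row(); a[pts_i[j + 1]] <- 1; a[pts_i[j]] <- -1; add(a, 0)
    }
    if (np >= 3) for (j in seq_len(np - 2)) {  # slopes nondecreasing
      d1 <- pts_x[j + 1] - pts_x[j]; d2 <- pts_x[j + 2] - pts_x[j + 1]
      a <- row()
      a[pts_i[j + 2]] <- d1; a[pts_i[j + 1]] <- -(d1 + d2); a[pts_i[j]] <- d2
      add(a, 0)
    }
    # monotonicity and concavity of (m, v_{s+1}..v_J) with values (w, z)
    qts_x <- c(m, v[s + seq_len(J - s)])
    qts_i <- c(iw, iz)
    nq <- length(qts_x)
    for (j in seq_len(nq - 1)) {
      a <- row(); a[qts_i[j + 1]] <- 1; a[qts_i[j]] <- -1; add(a, 0)
    }
    if (nq >= 3) for (j in seq_len(nq - 2)) {  # slopes nonincreasing
      d1 <- qts_x[j + 1] - qts_x[j]; d2 <- qts_x[j + 2] - qts_x[j + 1]
      a <- row()
      a[qts_i[j]] <- -d2; a[qts_i[j + 1]] <- (d1 + d2); a[qts_i[j + 2]] <- -d1
      add(a, 0)
    }
    lp_feasible(A, b, A1, b1)
  }

  feasible_at_point <- function(d, t) {
    # mode exactly at v_t: the jump at v_t belongs to the unimodal fit
    L <- lo(d); H <- hi(d)
    s <- t - 1L
    nv <- s + 1L + (J - s)  # y_1..y_{t-1}, w_minus, z_t..z_J
    iy <- seq_len(s)
    iwm <- s + 1L
    iz <- s + 1L + seq_len(J - s)
    A <- NULL; b <- NULL; A1 <- NULL; b1 <- NULL
    # rows: a %*% x >= bb; boot::simplex needs non-negative rhs, so rows
    # with bb < 0 are stored negated as <= constraints
    add <- function(a, bb) {
      if (bb >= 0) { A <<- rbind(A, a); b <<- c(b, bb) }
      else { A1 <<- rbind(A1, -a); b1 <<- c(b1, -bb) }
    }
    row <- function() numeric(nv)
    for (j in seq_len(s)) {
      a <- row(); a[iy[j]] <- 1; add(a, max(L[j], 0))
      a <- row(); a[iy[j]] <- -1; add(a, -H[j])
    }
    # w_minus = G(v_t-): below the left-limit band's upper edge
    a <- row(); a[iwm] <- -1; add(a, -H[t])
    a <- row(); a[iwm] <- 1; add(a, 0)
    # z_t = G(v_t): above the post-jump lower edge, upper edge relaxed
    a <- row(); a[iz[1]] <- 1; add(a, L[t])
    a <- row(); a[iz[1]] <- -1; add(a, -min(C[t] / n + d, 1))
    a <- row(); a[iz[1]] <- 1; a[iwm] <- -1; add(a, 0)  # jump up at mode
    for (k in seq_len(J - s)[-1]) {
      j <- s + k
      a <- row(); a[iz[k]] <- 1; add(a, L[j])
      a <- row(); a[iz[k]] <- -1; add(a, -min(H[j], 1))
    }
    pts_x <- c(v[seq_len(s)], v[t])
    pts_i <- c(iy, iwm)
    np <- length(pts_x)
    for (j in seq_len(np - 1)) {
      a <- row(); a[pts_i[j + 1]] <- 1; a[pts_i[j]] <- -1; add(a, 0)
    }
    if (np >= 3) for (j in seq_len(np - 2)) {
      d1 <- pts_x[j + 1] - pts_x[j]; d2 <- pts_x[j + 2] - pts_x[j + 1]
      a <- row()
      a[pts_i[j + 2]] <- d1; a[pts_i[j + 1]] <- -(d1 + d2); a[pts_i[j]] <- d2
      add(a, 0)
    }
    qts_x <- v[t - 1L + seq_len(J - t + 1L)]
    qts_i <- iz
    nq <- length(qts_x)
    for (j in seq_len(nq - 1)) {
      a <- row(); a[qts_i[j + 1]] <- 1; a[qts_i[j]] <- -1; add(a, 0)
    }
    if (nq >= 3) for (j in seq_len(nq - 2)) {
      d1 <- qts_x[j + 1] - qts_x[j]; d2 <- qts_x[j + 2] - qts_x[j + 1]
      a <- row()
      a[qts_i[j]] <- -d2; a[qts_i[j + 1]] <- (d1 + d2); a[qts_i[j + 2]] <- -d1
      add(a, 0)
    }
    lp_feasible(A, b, A1, b1)
  }

  span <- v[J] - v[1]
  feasible <- function(d) {
    for (t in seq_len(J)) if (feasible_at_point(d, t)) return(TRUE)
    for (s in 0:J) {
      gaps <- if (s == 0) v[1] - span * c(0.02, 0.5, 2)
      else if (s == J) v[J] + span * c(0.02, 0.5, 2)
      else v[s] + (v[s + 1] - v[s]) * c(0.02, 0.25, 0.5, 0.75, 0.98)
      for (m in gaps) if (feasible_split(d, s, m)) return(TRUE)
    }
    FALSE
  }

  dlo <- 0.5 / n; dhi <- 0.25
  if (feasible(dlo + 1e-9)) return(dlo)
  while (dhi - dlo > tol) {
    mid <- (dlo + dhi) / 2
    if (feasible(mid)) dhi <- mid else dlo <- mid
  }
  (dlo + dhi) / 2
}
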