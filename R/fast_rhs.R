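# Internal fast right-hand side.  Same mathematics as state_derivatives(),
# with all parameter lookups hoisted out of the per-step call; the test
# suite asserts exact agreement between the two implementations on random
# states (they must never diverge).

fast_deriv_factory <- function(params, ageing = FALSE) {
  p_Am <- params$p_Am; v <- params$v; kap <- params$kap
  p_M <- params$p_M; p_T <- params$p_T; k_J <- params$k_J
  E_G <- params$E_G
  asj <- attr(params, "mode") == "asj"
  E_Hb <- if (asj) params$E_Hb else -Inf
  has_EHp <- !is.null(params$E_Hp) && !is.na(params$E_Hp)
  E_Hp <- if (has_EHp) params$E_Hp else Inf
  h_a <- if (!is.null(params$h_a)) params$h_a else 0
  s_g <- if (!is.null(params$s_g)) params$s_g else 0
  s_M <- if (!is.null(params$s_M)) params$s_M else 1
  L_m <- kap * p_Am / p_M
  V_m <- (s_M * L_m)^3
  E_m <- p_Am / v
  do_age <- ageing && h_a > 0

  function(y, f, TC, s, TC_A = TC) {
    E <- y[[1]]; V <- y[[2]]; EH <- y[[3]]; ER <- y[[4]]
    L <- V^(1 / 3)
    V23 <- L * L
    pA <- if (asj && EH < E_Hb) 0 else f * s * p_Am * TC_A * V23
    pS <- (p_M * V + p_T * V23) * TC
    pC <- E * (E_G * s * v * TC / L + pS / V) / (kap * E / V + E_G)
    pJ <- k_J * EH * TC
    pG <- kap * pC - pS
    pR <- (1 - kap) * pC - pJ
    adult <- has_EHp && EH >= E_Hp

    dE <- pA - pC
    if (pG >= 0) {
      dV <- pG / E_G
      dER_starv <- 0
    } else {
      shortfall <- -pG
      if (adult && ER > 0) {
        dV <- 0
        dER_starv <- -shortfall
      } else {
        dV <- -shortfall / E_G
        dER_starv <- 0
      }
    }
    if (adult) {
      dEH <- 0
      dER <- pR + dER_starv
      if (dER < 0 && ER <= 0) {
        dV <- dV + dER / E_G
        dER <- 0
      }
    } else {
      dEH <- pR
      dER <- 0
      if (dEH < 0 && pG < 0) {
        dV <- dV + dEH / E_G
        dEH <- 0
      }
    }

    dq <- 0; dh <- 0; dlnS <- 0
    if (do_age) {
      r <- dV / V
      e <- E / (V * E_m)
      dq <- (y[[5]] * (V / V_m) * s_g + h_a) * e * (s * v * TC / L - r) - r * y[[5]]
      dh <- y[[5]] - r * y[[6]]
      dlnS <- -y[[6]]
    }
    c(dE, dV, dEH, dER, dq, dh, dlnS, pA, pS, pJ)
  }
}
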