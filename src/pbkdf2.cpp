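#include <Rcpp.h>
#include <openssl/evp.h>

// PBKDF2-HMAC-SHA512 key derivation. Returns lowercase hex of the
// derived key. `password` and `salt` are used byte-for-byte (ASCII).
// [[Rcpp::export(name = ".pbkdf2_sha512")]]
Rcpp::CharacterVector pbkdf2_sha512(Rcpp::CharacterVector password,
                                    std::string salt,
                                    int iterations,
                                    int dklen) {
  if (iterations < 1) Rcpp::stop("iterations must be >= 1");
  if (dklen < 1) Rcpp::stop("dklen must be >= 1");
  static const char* hx = "0123456789abcdef";
  int n = password.size();
  Rcpp::CharacterVector out(n);
  std::vector<unsigned char> dk(dklen);
  for (int i = 0; i < n; ++i) {
    std::string pw = Rcpp::as<std::string>(password[i]);
    int ok = PKCS5_PBKDF2_HMAC(pw.c_str(), pw.size(),
                               (const unsigned char*)salt.c_str(), salt.size(),
                               iterations, EVP_sha512(), dklen, dk.data());
    if (!ok) Rcpp::stop("PBKDF2 derivation failed");
    std::string hex(2 * dklen, '0');
    for (int j = 0; j < dklen; ++j) {
      hex[2 * j]     = hx[dk[j] >> 4];
      hex[2 * j + 1] = hx[dk[j] & 15];
    }
    out[i] = hex;
  }
  return out;
}
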