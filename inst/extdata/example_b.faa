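>s1
MKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDN
>s2
MKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDN
>s3
MKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDN
>s4
MKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDN
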