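>DRB1*04:01
PPGIFLINYPDYGWQIKNENWWIRIWWHKYVHKVMITMNWIYVQKQNKSCDIKQTHWLPK
RDIRKMMMDATLHTQKTYATKMIWCTHDPQGAQVA
>DRB1*04:02
PPGIFLINYPDYGGQIMNENWWIRIWWTKYVHKVMITMNWIYVQKQNKSCDIKQTHWLPK
RDIRKMMMDATIHTDETYATKMIWCTHDPQVAQVA
>DRB1*04:03
PPGIFLINYPDYGGQIMNENWWIRIWWTKYVHKVMITMNWIYVQKQNKSCDIKQTHWLPK
RDIRKMMMDATLHTQRTYETKMIWCTHDPQVAQVA
>DRB1*04:04
PPGIFLINYPDYGGQIMNENWWIRIWWTKYVHKVMFTMNWIYVQKQNKSCDIKQTHWLPK
RDIRKMMMDATLHTQRTYATKMIWCTHDPQVAQVA
>DRB1*04:05
PPGIFLINYPDYGGQIMNENWWIRIWWTKYVHKVMITMNWIYVQKQNKSCDIKQTHWLPK
RSIRKMMMDATLHTQRTYATKMIWCTHDPQGAQVA
>DRB1*04:06
PPGIFLINYPDYGGQIMNENWWIRIWWTKYVHKVMITMNWISVQKQNKSCDIKQTHWLPK
RDIRKMMMDATLHTQKTYATKMIWCTHDPQVAQVA
>DRB1*04:07
PPGIFLINYPDYGGQIMNENWWIRIWWTKYVHKVMITMNWIYVQKQNKSCDIKQTHWLPK
RDIRKMMMDATLHTQRTYETKMIWCTHDPQGAQVA
>DRB1*04:08
PPGIFLINYPDYGGQIMNENWWIRIWWTKYVHKVMFTMNWIYVQKQNKSCDIKQTHWLPK
RDIRKMMMDATLHTQRTYATKMIWCTHDPQVAQVA
>DRB1*04:10
PPGIFLINYPDYGGQIMNENWWIRIWWTKYVHKVMFTMNWIYVQKQNKSCDIKQTHWLPK
RDIRKMMMDATLHTQRTYATKMIWCTHDPQVAQVA
>DRB1*04:11
PPGIFLINYPDYGGQIMNENWWIRIWWTKYVHKVMITMNWIYVQKQNKSCDIKQTHWLPK
RDIRKMMMDATLHTQRTYATKMIWCTHDPQGAQVA
>DRB1*01:01
PPGIFGINYPDYGGNFMNEIWWIRIWWTKEVHKVMRFMNWIYVQKQNVHCLIEQTHWLPK
RDIRKMMWDATLKFQRTDAVAPIWDTHDSQGAQVA
>DRB1*03:01
PPGIFHINYHDYEFQNGNENCWIRIWWTTYVHKVMKTMNWCYVQKCNKSRDAKQTHWLGK
RDIRKMMMDATLHEQKTYRSKMLWCTFGPQVAQVA
>DRB1*03:02
PPGIFLINYPDEGGQIMNEQWYIRICCTKYVTKVMITMSWIYVQKQNGSCDDIQTHWLPK
RDIRKMMMDASLHTQKDIRTKTIHCTHQPKGAQVN
>DRB1*07:01
PPGIFCIMYPDTSMQIMNENWWARIWWTYYVHKVMRTMEWIYVFKWNKSCHITQTHWLPK
RDILGMMQQATIHTDRTYQTKMIWCTHDTQVAQEG
>DRB1*08:01
PPGIFMINYWDYGGQIMNENAWLRQWWTKYVHKVMRVCRWRYVWWQNNCCDIKQTHCLPK
RSIRKMMMDATLHIDRTYATKMIPCTHDPQGAFHE
>DRB1*15:01
PPGIFLINYDGPGGDIMNENWWIRIWLTEYVWKVMRTCNWIYVQKQNKSQDIKITPSLPR
RDIRKMMMIAEIHTQRMYATKWIWCTHDSQVAQCA
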